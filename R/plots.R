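#' Plot a binned methylation profile
#'
#' Draws the mean methylation level per bin, one line per stage, with the
#' upstream / body / downstream zones separated by dashed guides.
#'
#' @param profile Output of [binned_profile()].
#' @return A ggplot object.
#' @export
plot_profile <- function(profile) {
  breaks <- cumsum(rle(as.character(profile$zone[order(profile$bin)]))$lengths)
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$bin, y = .data$mean_level,
                               colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = utils::head(breaks, -1) + 0.5,
                        linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "bin (5' to 3')", y = "mean methylation level",
                  colour = "stage") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a genomic window track
#'
#' @param track Output of [window_track()].
#' @return A ggplot object (one panel per chromosome).
#' @export
plot_window_track <- function(track) {
  ggplot2::ggplot(track, ggplot2::aes(x = .data$win_start / 1e6, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "value") +
    ggplot2::theme_minimal()
}

#' Plot feature enrichment of differentially methylated sites
#'
#' Relative enrichment per feature class on a log2 scale; values above 1
#' mark over-representation of DM sites in the class.
#'
#' @param results An `enrichment` tibble (stacking several comparisons is
#'   fine; they become the fill aesthetic).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$feature, y = .data$relative_enrichment,
                               fill = .data$comparison)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = NULL, y = "relative enrichment (log2 scale)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
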