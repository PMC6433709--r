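#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a site-level differential methylation result
#'
#' @param x A `dm_sites` tibble from [dm_site_test()].
#' @param ... Unused.
#' @return A plain tibble of the per-site results.
#' @export
tidy.dm_sites <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a site-level differential methylation result
#'
#' @param x A `dm_sites` tibble from [dm_site_test()].
#' @param ... Unused.
#' @return Tibble with the comparison, tested site counts per context, DM
#'   counts and polarity split.
#' @export
glance.dm_sites <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)]) |>
    dplyr::group_by(.data$comparison, .data$context) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      n_dm = sum(.data$is_dm),
      dm_fraction = mean(.data$is_dm),
      n_hyper_in_a = sum(.data$polarity == "hyper_in_a"),
      n_hyper_in_b = sum(.data$polarity == "hyper_in_b"),
      .groups = "drop")
}

#' Tidy a region-level differential methylation result
#'
#' @param x A `dm_regions` tibble from [dm_region_test()].
#' @param ... Unused.
#' @return A plain tibble of the per-region results.
#' @export
tidy.dm_regions <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a region-level differential methylation result
#'
#' @param x A `dm_regions` tibble from [dm_region_test()].
#' @param ... Unused.
#' @return Tibble with region counts: supplied, tested (enough covered
#'   sites), and differentially methylated.
#' @export
glance.dm_regions <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)]) |>
    dplyr::group_by(.data$comparison, .data$context, .data$kind) |>
    dplyr::summarise(n_regions = dplyr::n(), n_tested = sum(.data$tested),
                     n_dm = sum(.data$is_dm), .groups = "drop")
}

#' Summarise a full pipeline run
#'
#' @param x A `methylome_analysis` object from [run_pipeline()].
#' @param ... Unused.
#' @return One-row tibble of site, island and DM call counts.
#' @export
glance.methylome_analysis <- function(x, ...) {
  tibble::tibble(
    n_sites = x$manifest$n_sites,
    n_cpg = x$manifest$n_sites_by_context$CpG %||% 0L,
    n_cph = x$manifest$n_sites_by_context$CpH %||% 0L,
    n_islands = x$manifest$n_islands,
    n_dm_sites = sum(unlist(x$manifest$n_dm_sites)),
    n_dm_regions = sum(unlist(x$manifest$n_dm_regions)))
}

#' Combined DM site table of a pipeline run
#'
#' @param x A `methylome_analysis` object from [run_pipeline()].
#' @param ... Unused.
#' @return Tibble stacking the per-comparison site-level results.
#' @export
tidy.methylome_analysis <- function(x, ...) {
  purrr::map(x$dm_sites, tidy) |> dplyr::bind_rows()
}

#' @export
print.methylome_analysis <- function(x, ...) {
  cat("<methylome_analysis>\n")
  cat("  sites retained:", x$manifest$n_sites, "\n")
  cat("  islands:", x$manifest$n_islands, "\n")
  cat("  DM sites per comparison:",
      paste(names(x$manifest$n_dm_sites),
            unlist(x$manifest$n_dm_sites), sep = "=", collapse = ", "), "\n")
  invisible(x)
}
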