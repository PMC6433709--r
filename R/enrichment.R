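#' Enrichment statistics from 2x2 counts
#'
#' Given the number of differentially methylated sites inside a feature
#' (`dm_in`), the total number of DM sites (`dm_total`), the number of
#' detected sites inside the feature (`sites_in`) and the total detected
#' sites (`sites_total`), computes the relative enrichment
#' `(dm_in / dm_total) / (sites_in / sites_total)`, the sample odds ratio
#' of the 2x2 table `[[dm_in, dm_out], [nondm_in, nondm_out]]`, and the
#' two-tail Fisher exact p-value of that table.
#'
#' @param dm_in,dm_total,sites_in,sites_total Count vectors (recycled).
#' @return Tibble with the four counts, `relative_enrichment`,
#'   `odds_ratio`, `p` and a logical `undefined` flag (set when
#'   `dm_total` or `sites_in` is 0, where the ratios are meaningless).
#' @export
#' @examples
#' enrichment_stats(3930, 85726, 57332, 1320853)
enrichment_stats <- function(dm_in, dm_total, sites_in, sites_total) {
  nn <- max(lengths(list(dm_in, dm_total, sites_in, sites_total)))
  dm_in <- rep_len(as.numeric(dm_in), nn)
  dm_total <- rep_len(as.numeric(dm_total), nn)
  sites_in <- rep_len(as.numeric(sites_in), nn)
  sites_total <- rep_len(as.numeric(sites_total), nn)
  if (any(dm_in > pmin(dm_total, sites_in))) {
    rlang::abort("dm_in cannot exceed dm_total or sites_in")
  }
  if (any(dm_total > sites_total | sites_in > sites_total)) {
    rlang::abort("totals are inconsistent")
  }
  a <- dm_in
  b <- dm_total - dm_in                 # DM outside the feature
  c <- sites_in - dm_in                 # non-DM inside
  d <- sites_total - sites_in - b       # non-DM outside
  undefined <- dm_total == 0 | sites_in == 0
  rel <- ifelse(undefined, NA_real_,
                (dm_in / dm_total) / (sites_in / sites_total))
  or <- ifelse(undefined | b == 0 | c == 0, NA_real_, a * d / (b * c))
  p <- fisher_exact_two_tail(a, b, c, d)
  tibble::tibble(dm_in = dm_in, dm_total = dm_total, sites_in = sites_in,
                 sites_total = sites_total, relative_enrichment = rel,
                 odds_ratio = or, p = p, undefined = undefined)
}

#' Feature enrichment of differentially methylated sites
#'
#' Tests each feature class (CGI island/shore/shelf, the five genic
#' features, and QTL membership) against its complement: are DM sites of
#' one context over- or under-represented inside the class relative to all
#' detected sites of that context?
#'
#' @param annot Annotated site tibble: `chrom`, `pos` plus any of
#'   `cgi_feature`, `genic_feature`, `qtl` (from [annotate_sites()]).
#' @param dm A `dm_sites` result ([dm_site_test()]); only rows with
#'   `is_dm` count as DM. Supply one context at a time or the full table --
#'   `context` selects the stratum.
#' @param context `"CpG"` or `"CpH"`; both `annot` and `dm` are filtered
#'   to it when they carry a `context` column.
#' @return An `enrichment` tibble: `feature`, `comparison`, `context`, the
#'   four counts and the statistics of [enrichment_stats()].
#' @export
feature_enrichment <- function(annot, dm, context = "CpG") {
  if ("context" %in% names(annot)) annot <- annot[annot$context == context, , drop = FALSE]
  comparison <- if ("comparison" %in% names(dm)) dm$comparison[1] else NA_character_
  if ("context" %in% names(dm)) dm <- dm[dm$context == context, , drop = FALSE]
  if ("is_dm" %in% names(dm)) dm <- dm[dm$is_dm, , drop = FALSE]
  is_dm <- paste(annot$chrom, annot$pos) %in% paste(dm$chrom, dm$pos)

  memberships <- list()
  if ("cgi_feature" %in% names(annot)) {
    for (f in c("island", "shore", "shelf")) {
      memberships[[f]] <- annot$cgi_feature == f
    }
  }
  if ("genic_feature" %in% names(annot)) {
    for (f in GENIC_FEATURES) memberships[[f]] <- annot$genic_feature == f
  }
  if ("qtl" %in% names(annot)) memberships[["qtl"]] <- annot$qtl
  if (!length(memberships)) rlang::abort("annot carries no feature columns")

  res <- purrr::imap(memberships, function(m, f) {
    st <- enrichment_stats(sum(is_dm & m), sum(is_dm), sum(m), length(m))
    dplyr::mutate(st, feature = f, .before = 1)
  }) |> dplyr::bind_rows()
  res <- dplyr::mutate(res, comparison = comparison, context = context,
                       .after = "feature")
  class(res) <- c("enrichment", class(tibble::tibble()))
  res
}

#' Arrange enrichment results as a report table
#'
#' One row per feature; per comparison, the DM count, the relative
#' enrichment rounded half-up to `digits` decimals, and the Fisher
#' p-value -- the shape of the published distribution tables.
#'
#' @param results An `enrichment` tibble, possibly covering several
#'   comparisons (rows are stacked [feature_enrichment()] outputs).
#' @param digits Decimals for the displayed enrichment (default 2).
#' @return A wide tibble: `feature`, `detected_sites`, then
#'   `<comparison>_dm`, `<comparison>_enrichment`, `<comparison>_p`.
#' @export
enrichment_report <- function(results, digits = 2) {
  base <- dplyr::distinct(results, .data$feature, detected_sites = .data$sites_in)
  wide <- results |>
    dplyr::mutate(enrichment = round_half_up(.data$relative_enrichment, digits)) |>
    dplyr::select("feature", "comparison", dm = "dm_in", "enrichment", "p") |>
    tidyr::pivot_wider(names_from = "comparison",
                       values_from = c("dm", "enrichment", "p"),
                       names_glue = "{comparison}_{.value}")
  dplyr::left_join(base, wide, by = "feature")
}
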