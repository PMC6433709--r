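#' Worked-example feature count tables
#'
#' Per-feature counts of detected and differentially methylated sites from
#' a published RRBS study of porcine hypothalamus methylomes across three
#' pubertal stages (Pre-, In-, Post-puberty; 3 gilts each): one table for
#' the CpG context (1,320,853 detected sites) and one for CpH (5,884,256).
#' Rows are the total, the three CGI-related classes, the five genic
#' features and QTL (age-at-puberty) membership; columns give the detected
#' site count and the DM count for each stage comparison. They serve as
#' worked-example inputs for [enrichment_stats()] and the DM percentage
#' arithmetic.
#'
#' @param context `"CpG"` or `"CpH"`.
#' @return Tibble with columns `feature`, `detected`, `dm_pre_vs_in`,
#'   `dm_in_vs_post`, `dm_pre_vs_post`.
#' @export
example_feature_counts <- function(context = c("CpG", "CpH")) {
  context <- match.arg(context)
  f <- if (context == "CpG") "hypothalamus_cpg_feature_counts.tsv" else
    "hypothalamus_cph_feature_counts.tsv"
  readr::read_tsv(system.file("extdata", f, package = "methylrrbs", mustWork = TRUE),
                  col_types = "cdddd", progress = FALSE)
}
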