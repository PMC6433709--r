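#' Assign each site to one of five genic features
#'
#' Every site receives exactly one label with precedence
#' exon > intron > upstream > downstream > intergenic. Upstream is the 5 kb
#' region before the TSS and downstream the 5 kb region after the TES, both
#' strand-aware. Sites on chromosomes absent from the gene models are
#' labelled intergenic with a warning.
#'
#' @param sites Tibble with columns `chrom` and `pos` (1-based).
#' @param genes Gene-model tibble (see [read_gene_table()]).
#' @param flank Flank width in bp (default 5000).
#' @return `sites` with an added factor column `genic_feature` with levels
#'   upstream, exon, intron, downstream, intergenic.
#' @export
assign_genic_feature <- function(sites, genes, flank = 5000) {
  check_genes(genes)
  if (nrow(genes) > 0 && length(setdiff(unique(sites$chrom), unique(genes$chrom)))) {
    rlang::warn("sites on chromosomes without gene models are labelled intergenic")
  }
  exon_iv <- dplyr::bind_rows(purrr::map2(genes$exons, genes$chrom, function(ex, ch) {
    new_intervals(rep(ch, nrow(ex)), ex$start, ex$end)
  }))
  body_iv <- new_intervals(genes$chrom, genes$start, genes$end)
  plus <- genes$strand == "+"
  up_iv <- new_intervals(
    genes$chrom,
    ifelse(plus, genes$start - flank, genes$end),
    ifelse(plus, genes$start, genes$end + flank))
  down_iv <- new_intervals(
    genes$chrom,
    ifelse(plus, genes$end, genes$start - flank),
    ifelse(plus, genes$end + flank, genes$start))
  lab <- rep("intergenic", nrow(sites))
  lab[sites_in_intervals(sites$chrom, sites$pos, down_iv)] <- "downstream"
  lab[sites_in_intervals(sites$chrom, sites$pos, up_iv)] <- "upstream"
  lab[sites_in_intervals(sites$chrom, sites$pos, body_iv)] <- "intron"
  lab[sites_in_intervals(sites$chrom, sites$pos, exon_iv)] <- "exon"
  sites$genic_feature <- factor(lab, levels = GENIC_FEATURES)
  sites
}

GENIC_FEATURES <- c("upstream", "exon", "intron", "downstream", "intergenic")
CGI_FEATURES <- c("island", "shore", "shelf", "open_sea")

#' Assign each site to a CGI-related class
#'
#' @param sites Tibble with columns `chrom` and `pos` (1-based).
#' @param annotation A `cgi_annotation` object from
#'   [derive_shores_shelves()], or a list with interval tibbles `islands`,
#'   `shores`, `shelves`.
#' @return `sites` with an added factor column `cgi_feature` with levels
#'   island, shore, shelf, open_sea.
#' @export
assign_cgi_feature <- function(sites, annotation) {
  lab <- rep("open_sea", nrow(sites))
  lab[sites_in_intervals(sites$chrom, sites$pos, annotation$shelves)] <- "shelf"
  lab[sites_in_intervals(sites$chrom, sites$pos, annotation$shores)] <- "shore"
  lab[sites_in_intervals(sites$chrom, sites$pos, annotation$islands)] <- "island"
  sites$cgi_feature <- factor(lab, levels = CGI_FEATURES)
  sites
}

#' Genes whose extended span contains each site
#'
#' The extended span of a gene is its body plus `flank` bp on both sides,
#' the region used for calling genes differentially methylated and for the
#' "regarding gene" assignments. A site can fall in several genes' spans
#' or in none.
#'
#' @param sites Tibble with columns `chrom` and `pos` (1-based).
#' @param genes Gene-model tibble.
#' @param flank Flank width in bp (default 5000).
#' @return Tibble of (`chrom`, `pos`, `gene_id`) pairs.
#' @export
genes_for_site <- function(sites, genes, flank = 5000) {
  check_genes(genes)
  out <- list()
  for (ch in unique(genes$chrom)) {
    ix <- which(sites$chrom == ch)
    if (!length(ix)) next
    ord <- ix[order(sites$pos[ix])]
    p0 <- sites$pos[ord] - 1
    gs <- genes[genes$chrom == ch, , drop = FALSE]
    for (g in seq_len(nrow(gs))) {
      lo <- gs$start[g] - flank
      hi <- gs$end[g] + flank
      i1 <- findInterval(lo - 0.5, p0) + 1L
      i2 <- findInterval(hi - 0.5, p0)
      if (i2 >= i1) {
        hit <- ord[i1:i2]
        out[[length(out) + 1L]] <- tibble::tibble(
          chrom = ch, pos = sites$pos[hit], gene_id = gs$gene_id[g])
      }
    }
  }
  if (!length(out)) return(tibble::tibble(chrom = character(), pos = integer(),
                                          gene_id = character()))
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$pos, .data$gene_id)
}

#' Flag sites inside QTL intervals
#'
#' Overlapping QTL intervals are merged first, so a site covered by two
#' overlapping QTLs counts once.
#'
#' @param sites Tibble with columns `chrom` and `pos` (1-based).
#' @param qtls Interval tibble (`chrom`, `start`, `end`).
#' @return `sites` with an added logical column `qtl`.
#' @export
overlaps_qtl <- function(sites, qtls) {
  sites$qtl <- sites_in_intervals(sites$chrom, sites$pos, qtls)
  sites
}

#' Annotate sites with genic, CGI and QTL features in one call
#'
#' @param sites Tibble with columns `chrom` and `pos`.
#' @param genes Gene-model tibble.
#' @param cgi_annotation A `cgi_annotation` object (or `NULL` to skip).
#' @param qtls QTL interval tibble (or `NULL` to skip).
#' @param flank Genic flank width in bp (default 5000).
#' @return `sites` with added columns `genic_feature`, and where inputs are
#'   given `cgi_feature` and `qtl`.
#' @export
annotate_sites <- function(sites, genes, cgi_annotation = NULL, qtls = NULL,
                           flank = 5000) {
  sites <- assign_genic_feature(sites, genes, flank = flank)
  if (!is.null(cgi_annotation)) sites <- assign_cgi_feature(sites, cgi_annotation)
  if (!is.null(qtls)) sites <- overlaps_qtl(sites, qtls)
  sites
}
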