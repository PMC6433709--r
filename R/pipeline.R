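#' Configuration for the end-to-end methylome analysis pipeline
#'
#' Inputs may be file paths (FASTA genome, BED12/TSV genes, BED islands and
#' QTLs, CGmap sample files) or the in-memory objects the rest of the
#' package uses; thresholds default to the analysis' standard values.
#'
#' @param genome Named character vector of sequences, or FASTA path.
#' @param genes Gene-model tibble or path ([read_gene_table()]).
#' @param samples Named list of CGmap tibbles or named vector of paths.
#' @param sample_table Tibble (`sample`, `stage`, `replicate`); parsed from
#'   sample names when `NULL`.
#' @param cgi Island interval tibble or BED path; when `NULL`, islands are
#'   called from the genome with [call_cgis_genome()].
#' @param qtl QTL interval tibble or BED path (optional).
#' @param min_cov Minimum per-sample site coverage (default 5).
#' @param delta_min Strict site methylation-difference threshold
#'   (default 0.20).
#' @param q_max Inclusive FDR threshold (default 0.05).
#' @param min_sites Minimum covered sites per tested region (default 20).
#' @param window_width Window-track width in bp (default 1e6).
#' @param flank_gene,flank_cgi Flank widths in bp (defaults 5000, 2000).
#' @param outdir Optional output directory for TSV/BED exports and the
#'   manifest.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, genes, samples, sample_table = NULL,
                            cgi = NULL, qtl = NULL, min_cov = 5,
                            delta_min = 0.20, q_max = 0.05, min_sites = 20,
                            window_width = 1e6, flank_gene = 5000,
                            flank_cgi = 2000, outdir = NULL) {
  cfg <- as.list(environment())
  thr <- c(min_cov, delta_min, q_max, min_sites, window_width, flank_gene, flank_cgi)
  if (any(thr < 0) || min_cov <= 0 || window_width <= 0) {
    rlang::abort("thresholds must be positive")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full methylome analysis pipeline
#'
#' Executes, in order: site loading and coverage/co-existence filtering;
#' CGI annotation (calling islands when none are supplied) with shore and
#' shelf derivation; genic, CGI and QTL site annotation; binned gene and
#' island profiles and megabase window tracks; site-level differential
#' methylation for the three stage comparisons in both contexts;
#' region-level tests for islands (DMIs) and genes with 5 kb flanks (DMGs);
#' DM-regarding-gene sets; and feature enrichment. When `outdir` is set,
#' every table is written as TSV/BED together with a JSON manifest
#' recording thresholds, row counts and file checksums.
#'
#' @param config A [pipeline_config()] object.
#' @return A `methylome_analysis` list: `site_matrix`, `annotation`
#'   (annotated site tibble), `cgi_annotation`, `profiles`, `windows`,
#'   `dm_sites`, `dm_regions`, `dm_genes`, `enrichment`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "load inputs"
  res <- tryCatch({
    genome <- if (is.character(config$genome) && length(config$genome) == 1 &&
                  file.exists(config$genome)) read_fasta(config$genome) else config$genome
    genes <- if (is.character(config$genes)) read_gene_table(config$genes) else config$genes
    chrom_lengths <- stats::setNames(nchar(genome), names(genome))

    stage <- "cgi annotation"
    islands <- if (is.null(config$cgi)) {
      call_cgis_genome(genome)
    } else if (is.character(config$cgi)) read_bed(config$cgi) else config$cgi
    cgi_ann <- derive_shores_shelves(islands[, c("chrom", "start", "end")],
                                     chrom_lengths, flank = config$flank_cgi)

    stage <- "load and filter sites"
    sm <- load_and_filter(config$samples, config$sample_table,
                          min_cov = config$min_cov)

    stage <- "site annotation"
    qtls <- if (is.character(config$qtl)) read_bed(config$qtl) else config$qtl
    annot <- annotate_sites(
      sm[, c("chrom", "pos", "strand", "context")], genes,
      cgi_annotation = cgi_ann, qtls = qtls, flank = config$flank_gene)

    stage <- "profiles and windows"
    profiles <- list()
    for (ctx in unique(sm$context)) {
      profiles[[paste0("gene_", ctx)]] <-
        binned_profile(genes, sm, scheme = "gene", context = ctx)
      profiles[[paste0("cgi_", ctx)]] <-
        binned_profile(cgi_ann$islands, sm, scheme = "cgi", context = ctx)
    }
    gl <- group_levels(sm)
    windows <- list(site_density = purrr::map(
      stats::setNames(nm = unique(sm$context)),
      function(ctx) window_track(sm[sm$context == ctx, ], chrom_lengths,
                                 width = config$window_width)))
    for (s in unique(sample_table(sm)$stage)) {
      d <- gl[gl$context == "CpG", c("chrom", "pos", s)]
      names(d)[3] <- "level"
      windows[[paste0("cpg_level_", s)]] <-
        window_track(d, chrom_lengths, width = config$window_width,
                     mode = "mean_level")
    }

    stage <- "differential methylation"
    gene_spans <- tibble::tibble(
      region_id = genes$gene_id, kind = "gene", chrom = genes$chrom,
      start = genes$start - config$flank_gene, end = genes$end + config$flank_gene)
    island_regions <- dplyr::mutate(
      cgi_ann$islands[, c("chrom", "start", "end")],
      region_id = sprintf("cgi%05d", dplyr::row_number()), kind = "CGI")
    dm_sites <- list(); dm_regions <- list(); dm_genes <- list(); enr <- list()
    for (cname in COMPARISONS$comparison) {
      ds <- dm_site_test(sm, cname, delta_min = config$delta_min,
                         q_max = config$q_max)
      dm_sites[[cname]] <- ds
      windows[[paste0("dm_density_", cname)]] <-
        window_track(ds[ds$is_dm, c("chrom", "pos")], chrom_lengths,
                     width = config$window_width)
      for (ctx in unique(sm$context)) {
        key <- paste0(cname, "_", ctx)
        dm_regions[[paste0(key, "_CGI")]] <- dm_region_test(
          island_regions, sm, cname, context = ctx,
          min_sites = config$min_sites, q_max = config$q_max)
        dm_regions[[paste0(key, "_gene")]] <- dm_region_test(
          gene_spans, sm, cname, context = ctx,
          min_sites = config$min_sites, q_max = config$q_max)
        dm_genes[[key]] <- dm_regarding_genes(
          ds[ds$context == ctx, ], genes, flank = config$flank_gene)
        enr[[key]] <- feature_enrichment(annot, ds, context = ctx)
      }
    }

    stage <- "manifest"
    manifest <- list(
      package = as.character(utils::packageVersion("methylrrbs")),
      thresholds = list(min_cov = config$min_cov, delta_min = config$delta_min,
                        q_max = config$q_max, min_sites = config$min_sites,
                        window_width = config$window_width,
                        flank_gene = config$flank_gene,
                        flank_cgi = config$flank_cgi),
      n_sites = nrow(sm),
      n_sites_by_context = as.list(table(sm$context)),
      n_islands = nrow(cgi_ann$islands),
      n_dm_sites = purrr::map(dm_sites, ~ sum(.x$is_dm)),
      n_dm_regions = purrr::map(dm_regions, ~ sum(.x$is_dm)))

    out <- list(site_matrix = sm, annotation = annot, cgi_annotation = cgi_ann,
                profiles = profiles, windows = windows, dm_sites = dm_sites,
                dm_regions = dm_regions, dm_genes = dm_genes,
                enrichment = enr, manifest = manifest)
    class(out) <- "methylome_analysis"
    out
  }, error = function(e) {
    rlang::abort(paste0("pipeline failed at stage '", stage, "': ",
                        conditionMessage(e)))
  })

  if (!is.null(config$outdir)) {
    res$manifest$files <- write_analysis(res, config$outdir)
    jsonlite::write_json(res$manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

write_analysis <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    path <- file.path(outdir, name)
    readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
    path
  }
  paths <- c(
    w(res$site_matrix, "site_matrix.tsv"),
    w(res$annotation, "site_annotation.tsv"),
    write_bed(res$cgi_annotation$islands[, c("chrom", "start", "end")],
              file.path(outdir, "islands.bed")),
    write_bed(res$cgi_annotation$shores, file.path(outdir, "shores.bed")),
    write_bed(res$cgi_annotation$shelves, file.path(outdir, "shelves.bed")),
    purrr::imap_chr(res$profiles, ~ w(.x, paste0("profile_", .y, ".tsv"))),
    purrr::imap_chr(res$windows$site_density %||% list(),
                    ~ w(.x, paste0("windows_density_", .y, ".tsv"))),
    purrr::imap_chr(res$dm_sites, ~ w(.x, paste0("dm_sites_", .y, ".tsv"))),
    purrr::imap_chr(res$dm_regions, ~ w(.x, paste0("dm_regions_", .y, ".tsv"))),
    purrr::imap_chr(res$enrichment, ~ w(.x, paste0("enrichment_", .y, ".tsv"))))
  for (k in names(res$dm_genes)) {
    p <- file.path(outdir, paste0("dm_genes_", k, ".txt"))
    writeLines(res$dm_genes[[k]], p)
    paths <- c(paths, p)
  }
  md5 <- tools::md5sum(paths)
  purrr::map2(paths, md5, ~ list(path = basename(.x), md5 = unname(.y))) |>
    stats::setNames(basename(paths))
}
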