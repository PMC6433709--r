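#' Configuration for the synthetic RRBS methylome generator
#'
#' The defaults describe the study conditions the generator emulates: a
#' 3-stage (Pre-, In-, Post-pubertal) by 3-replicate RRBS design on a small
#' genome whose MspI-fragment-restricted coverage yields on the order of
#' 2e4 CpG and 5e4 CpH sites; high bimodal CpG methylation (low inside CpG
#' islands, high in the open sea, site-averaged genome level near 53%),
#' very low CpH methylation (~0.7%), a small monotone Pre > In > Post
#' global decrease, beta-distributed replicate-level noise, and planted
#' differentially methylated sites and regions recorded as ground truth.
#'
#' @param seed Integer seed; identical configurations give byte-identical
#'   outputs.
#' @param n_chrom,chrom_length Number of chromosomes and their length (bp).
#' @param n_genes,n_cgis,n_qtls Number of planted gene models, CpG islands
#'   and QTL intervals (totals across the genome).
#' @param frag_min,frag_max In-silico MspI size-selection window in bp.
#' @param mean_coverage Mean reads per covered cytosine.
#' @param coverage_dispersion Negative-binomial size (shape) of per-site
#'   coverage; smaller is more overdispersed.
#' @param cpg_level_island,cpg_level_open Baseline CpG methylation inside
#'   planted islands and in the open sea.
#' @param cph_level Baseline CpH methylation.
#' @param stage_deltas Named additive shifts of the CpG baseline per stage,
#'   non-increasing Pre to Post. For CpH sites the shift is rescaled by
#'   `cph_level / cpg_level_open` so the tiny CpH baseline declines
#'   proportionally instead of being clipped at zero.
#' @param beta_binomial_rho Intra-group overdispersion: each replicate's
#'   site probability is drawn from a Beta with mean p and correlation
#'   parameter rho.
#' @param dm_site_fraction Fraction of sites (per context) planted as
#'   differentially methylated.
#' @param dm_effect Absolute planted site effect (methylation shift in one
#'   stage).
#' @param dm_region_count Number of planted differentially methylated
#'   regions (half islands, half genes).
#' @param dm_region_effect Absolute planted region effect.
#' @param background_gc,island_gc Base composition of the background
#'   sequence and of planted islands.
#' @param island_length,gene_length Length ranges (bp) for planted islands
#'   and genes.
#' @param promoter_cgi_fraction Fraction of islands anchored at gene TSSs
#'   (900 bp upstream, 100 bp into the body), mimicking promoter islands.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_length = 1500000,
                       n_genes = 80L,
                       n_cgis = 120L,
                       n_qtls = 8L,
                       frag_min = 110L,
                       frag_max = 220L,
                       mean_coverage = 20,
                       coverage_dispersion = 5,
                       cpg_level_island = 0.22,
                       cpg_level_open = 0.87,
                       cph_level = 0.007,
                       stage_deltas = c(Pre = 0, In = -0.005, Post = -0.015),
                       beta_binomial_rho = 0.01,
                       dm_site_fraction = 0.02,
                       dm_effect = 0.5,
                       dm_region_count = 12L,
                       dm_region_effect = 0.3,
                       background_gc = 0.40,
                       island_gc = 0.66,
                       island_length = c(1100, 1600),
                       gene_length = c(3000, 8000),
                       promoter_cgi_fraction = 0.6) {
  cfg <- as.list(environment())
  if (cfg$frag_min >= cfg$frag_max) rlang::abort("frag_min must be < frag_max")
  fr <- c(cfg$cpg_level_island, cfg$cpg_level_open, cfg$cph_level,
          cfg$beta_binomial_rho, cfg$dm_site_fraction, cfg$dm_effect,
          cfg$dm_region_effect, cfg$background_gc, cfg$island_gc,
          cfg$promoter_cgi_fraction)
  if (any(fr < 0 | fr > 1)) rlang::abort("all fractions must lie in [0, 1]")
  if (!all(names(cfg$stage_deltas) == STAGES)) {
    rlang::abort("stage_deltas must be named Pre, In, Post")
  }
  if (is.unsorted(rev(cfg$stage_deltas))) {
    rlang::abort("stage_deltas must be non-increasing Pre -> In -> Post")
  }
  structure(cfg, class = "sim_config")
}

sample_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate a synthetic genome with gene models, islands and QTLs
#'
#' Chromosome sequences are drawn with a moderately AT-rich background so
#' that, by construction, the CpG-island criteria fail outside planted
#' islands and hold inside them (islands are CG-balanced at `island_gc`, so
#' their observed/expected CpG ratio is close to 1). Genes are non-
#' overlapping, strand-assigned, and begin and end with an exon; most
#' islands are anchored at a gene TSS. All planted features are recorded as
#' ground truth.
#'
#' @param config A [sim_config()] object.
#' @return List with `genome` (named character vector), `genes`
#'   (gene-model tibble), `cgis` (island truth intervals with `name`),
#'   `qtls` (interval tibble), and `chrom_lengths`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1))
  chroms <- paste0("chr", seq_len(config$n_chrom))
  len <- config$chrom_length
  genes_per_chrom <- diff(round(seq(0, config$n_genes, length.out = config$n_chrom + 1)))
  cgis_per_chrom <- diff(round(seq(0, config$n_cgis, length.out = config$n_chrom + 1)))
  n_prom_total <- round(config$promoter_cgi_fraction * config$n_cgis)

  cell_need <- max(config$gene_length) + 2 * 7000
  if (any(genes_per_chrom > 0) && len / max(genes_per_chrom, 1) < cell_need) {
    rlang::abort("requested genes do not fit in the genome; increase chrom_length")
  }

  genome <- character(config$n_chrom); names(genome) <- chroms
  genes <- list(); cgis <- list(); qtls <- list()
  gid <- 0L; cid <- 0L

  for (ci in seq_len(config$n_chrom)) {
    ch <- chroms[ci]
    chars <- sample_bases(len, config$background_gc)

    # genes: one per cell, away from the cell edges so 5 kb flanks are clean
    ng <- genes_per_chrom[ci]
    g_tbl <- NULL
    if (ng > 0) {
      cell <- len / ng
      glen <- round(stats::runif(ng, config$gene_length[1], config$gene_length[2]))
      off <- round(stats::runif(ng, 7000, cell - glen - 7000))
      gstart <- round((seq_len(ng) - 1) * cell) + off
      strand <- sample(c("+", "-"), ng, replace = TRUE)
      exons <- purrr::map2(gstart, glen, function(s, L) {
        k <- sample(2:5, 1)
        w <- stats::runif(2 * k - 1, 0.5, 1.5)
        seg <- 50 + floor((L - 50 * (2 * k - 1)) * w / sum(w))
        seg[1] <- seg[1] + (L - sum(seg))  # absorb rounding into exon 1
        b <- s + c(0, cumsum(seg))
        tibble::tibble(start = b[seq(1, 2 * k - 1, by = 2)],
                       end = b[seq(2, 2 * k, by = 2)])
      })
      g_tbl <- tibble::tibble(
        gene_id = sprintf("gene%04d", gid + seq_len(ng)),
        chrom = ch, strand = strand,
        start = gstart, end = gstart + glen, exons = exons)
      gid <- gid + ng
      genes[[ci]] <- g_tbl
    }

    # islands: promoter-anchored first, remainder in intergenic space
    nc <- cgis_per_chrom[ci]
    n_prom <- min(round(n_prom_total * nc / max(config$n_cgis, 1)), ng)
    c_iv <- NULL
    if (nc > 0) {
      ilen <- round(stats::runif(nc, config$island_length[1], config$island_length[2]))
      istart <- numeric(0); iend <- numeric(0)
      if (n_prom > 0) {
        host <- sample(seq_len(ng), n_prom)
        tss_plus <- g_tbl$strand[host] == "+"
        s <- ifelse(tss_plus, g_tbl$start[host] - (ilen[seq_len(n_prom)] - 100),
                    g_tbl$end[host] - 100)
        istart <- c(istart, s); iend <- c(iend, s + ilen[seq_len(n_prom)])
      }
      n_free <- nc - n_prom
      if (n_free > 0) {
        blocked <- new_intervals(ch, c(if (ng) g_tbl$start - 6000 else numeric(0), istart - 2000),
                                 c(if (ng) g_tbl$end + 6000 else numeric(0), iend + 2000))
        free <- subtract_intervals(new_intervals(ch, 0, len), blocked)
        placed <- 0L; tries <- 0L
        while (placed < n_free && tries < 20000L) {
          tries <- tries + 1L
          L <- ilen[n_prom + placed + 1]
          fi <- free[free$end - free$start >= L + 4000, , drop = FALSE]
          if (!nrow(fi)) break
          row <- fi[sample.int(nrow(fi), 1), ]
          s <- round(stats::runif(1, row$start + 2000, row$end - L - 2000))
          istart <- c(istart, s); iend <- c(iend, s + L)
          placed <- placed + 1L
          free <- subtract_intervals(free, new_intervals(ch, s - 2000, s + L + 2000))
        }
        if (placed < n_free) {
          rlang::abort("requested islands do not fit in the genome; increase chrom_length")
        }
      }
      ord <- order(istart)
      istart <- istart[ord]; iend <- iend[ord]
      for (k in seq_along(istart)) {
        chars[(istart[k] + 1):iend[k]] <- sample_bases(iend[k] - istart[k], config$island_gc)
      }
      cid_new <- cid + seq_along(istart)
      c_iv <- tibble::tibble(chrom = ch, start = istart, end = iend,
                             name = sprintf("cgi%04d", cid_new))
      cid <- cid + length(istart)
      cgis[[ci]] <- c_iv
    }

    # QTL intervals: free placement, overlaps with anything allowed
    nq <- diff(round(seq(0, config$n_qtls, length.out = config$n_chrom + 1)))[ci]
    if (nq > 0) {
      qlen <- round(stats::runif(nq, 50000, min(200000, len / 2)))
      qs <- round(stats::runif(nq, 0, len - qlen))
      qtls[[ci]] <- tibble::tibble(chrom = ch, start = qs, end = qs + qlen,
                                   name = sprintf("qtl%02d_%s", seq_len(nq), ch))
    }
    genome[ci] <- paste(chars, collapse = "")
  }

  list(
    genome = genome,
    genes = dplyr::bind_rows(genes),
    cgis = dplyr::bind_rows(cgis),
    qtls = dplyr::bind_rows(qtls),
    chrom_lengths = stats::setNames(rep(len, config$n_chrom), chroms)
  )
}

#' In-silico MspI digestion with size selection
#'
#' MspI cuts at C^CGG. Fragments are the intervals between consecutive cut
#' sites on a chromosome (chromosome ends are not fragment boundaries),
#' retained when their length falls within `[frag_min, frag_max]` -- the
#' size-selection step of RRBS library preparation.
#'
#' @param sequence A single uppercase sequence string.
#' @param frag_min,frag_max Retained fragment length bounds in bp
#'   (defaults 110 and 220).
#' @return Interval tibble (`start`, `end`), 0-based half-open, sorted and
#'   non-overlapping. Empty when the sequence has fewer than two cut sites.
#' @export
msp1_digest <- function(sequence, frag_min = 110L, frag_max = 220L) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0) {
    rlang::abort("sequence must be a single non-empty string")
  }
  m <- gregexpr("CCGG", sequence, fixed = TRUE)[[1]]
  if (m[1] == -1 || length(m) < 2) {
    return(tibble::tibble(start = numeric(0), end = numeric(0)))
  }
  cuts <- as.numeric(m)  # cut between C and CGG: 0-based boundary = match pos
  s <- cuts[-length(cuts)]
  e <- cuts[-1]
  keep <- (e - s) >= frag_min & (e - s) <= frag_max
  tibble::tibble(start = s[keep], end = e[keep])
}

# enumerate every cytosine (both strands) inside retained fragments;
# positions are 1-based Watson-strand coordinates
enumerate_sites <- function(chars, fragments, chrom = "chr1") {
  n <- length(chars)
  in_frag <- logical(n)
  if (nrow(fragments)) {
    idx <- unlist(purrr::map2(fragments$start + 1, fragments$end, seq.int))
    in_frag[idx] <- TRUE
  }
  pc <- which(chars == "C" & in_frag); pc <- pc[pc < n]
  pg <- which(chars == "G" & in_frag); pg <- pg[pg > 1]

  nxt <- chars[pc + 1]
  nxt2 <- ifelse(pc + 2 <= n, chars[pmin(pc + 2, n)], "N")
  plus <- tibble::tibble(
    chrom = chrom, pos = pc, strand = "+",
    context = ifelse(nxt == "G", "CpG", "CpH"),
    context_class = ifelse(nxt == "G", "CG", ifelse(nxt2 == "G", "CHG", "CHH")),
    dinucleotide = paste0("C", nxt)
  )
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  prv <- chars[pg - 1]
  prv2 <- ifelse(pg - 2 >= 1, chars[pmax(pg - 2, 1)], "N")
  minus <- tibble::tibble(
    chrom = chrom, pos = pg, strand = "-",
    context = ifelse(prv == "C", "CpG", "CpH"),
    context_class = ifelse(prv == "C", "CG", ifelse(prv2 == "C", "CHG", "CHH")),
    dinucleotide = paste0("C", comp[prv])
  )
  dplyr::arrange(dplyr::bind_rows(plus, minus), .data$pos)
}

# baseline per-site methylation probability for a given stage
site_probability <- function(sites, config, islands, stage, dm_sites = NULL,
                             dm_regions = NULL) {
  is_cpg <- sites$context == "CpG"
  in_island <- sites_in_intervals(sites$chrom, sites$pos, islands)
  p <- ifelse(is_cpg,
              ifelse(in_island, config$cpg_level_island, config$cpg_level_open),
              config$cph_level)
  delta <- config$stage_deltas[[stage]]
  p <- p + ifelse(is_cpg, delta, delta * config$cph_level / config$cpg_level_open)
  if (!is.null(dm_sites) && nrow(dm_sites)) {
    hit <- dm_sites[dm_sites$target_stage == stage, , drop = FALSE]
    if (nrow(hit)) {
      m <- match(paste(sites$chrom, sites$pos), paste(hit$chrom, hit$pos))
      has <- !is.na(m)
      p[has] <- p[has] + hit$effect[m[has]]
    }
  }
  if (!is.null(dm_regions) && nrow(dm_regions)) {
    for (k in which(dm_regions$target_stage == stage)) {
      inr <- sites$chrom == dm_regions$chrom[k] &
        sites$pos - 1 >= dm_regions$start[k] & sites$pos - 1 < dm_regions$end[k]
      p[inr] <- p[inr] + dm_regions$effect[k]
    }
  }
  pmin(pmax(p, 0), 1)
}

#' Simulate per-cytosine methylation counts for one sample
#'
#' For every cytosine (both strands) inside a retained fragment, coverage
#' is drawn from a negative binomial, the per-site methylation probability
#' is the context baseline plus the stage shift plus any planted effect
#' (clipped to `[0, 1]`), a replicate-level Beta perturbation with
#' correlation `beta_binomial_rho` is applied, and methylated reads are
#' binomial. Sites drawn with zero coverage are not emitted.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param fragments Interval tibble with a `chrom` column (retained
#'   fragments from [msp1_digest()]).
#' @param config A [sim_config()] object.
#' @param stage One of `"Pre"`, `"In"`, `"Post"`.
#' @param replicate Replicate index (1-based).
#' @param islands Planted island intervals (methylation baseline regions).
#' @param dm_sites,dm_regions Planted differential-methylation plans
#'   (tibbles with `target_stage` and `effect`), or `NULL`.
#' @param sites Optional pre-enumerated site table (from internal
#'   enumeration) to avoid rescanning the genome.
#' @return A CGmap-style tibble: `chrom`, `base`, `pos`, `context_class`,
#'   `dinucleotide`, `level`, `meth`, `total`.
#' @export
simulate_counts <- function(genome, fragments, config, stage, replicate,
                            islands = NULL, dm_sites = NULL, dm_regions = NULL,
                            sites = NULL) {
  stopifnot(inherits(config, "sim_config"))
  check_stage(stage)
  if (is.null(sites)) {
    sites <- purrr::imap(genome, function(s, ch) {
      enumerate_sites(strsplit(s, "", fixed = TRUE)[[1]],
                      fragments[fragments$chrom == ch, , drop = FALSE], chrom = ch)
    }) |> dplyr::bind_rows()
  }
  si <- match(stage, STAGES)
  set.seed(derive_seed(config$seed, 100 + si * 10 + replicate))
  p <- site_probability(sites, config, islands, stage, dm_sites, dm_regions)
  rho <- config$beta_binomial_rho
  if (rho > 0) {
    inner <- p > 0 & p < 1
    shape <- (1 - rho) / rho
    p[inner] <- stats::rbeta(sum(inner), p[inner] * shape, (1 - p[inner]) * shape)
  }
  total <- stats::rnbinom(nrow(sites), size = config$coverage_dispersion,
                          mu = config$mean_coverage)
  meth <- stats::rbinom(nrow(sites), total, p)
  keep <- total > 0
  tibble::tibble(
    chrom = sites$chrom[keep],
    base = ifelse(sites$strand[keep] == "+", "C", "G"),
    pos = sites$pos[keep],
    context_class = sites$context_class[keep],
    dinucleotide = sites$dinucleotide[keep],
    level = meth[keep] / total[keep],
    meth = meth[keep],
    total = total[keep]
  )
}

#' Simulate a complete multi-sample RRBS methylome with ground truth
#'
#' Generates the genome and annotations, digests it in silico, plants
#' comparison-specific differentially methylated sites and regions among
#' the cytosines covered by retained fragments, and simulates one
#' CGmap-style count table per sample of the 3-stage x 3-replicate design.
#'
#' @param config A [sim_config()] object.
#' @param outdir Optional directory; when given, writes `genome.fa`,
#'   `genes.bed` (BED12), `qtls.bed`, `cgis_truth.bed`, one
#'   `<sample>.cgmap.tsv` per sample, `sample_table.tsv` and truth tables.
#' @return List with `genome`, `genes`, `cgis`, `qtls`, `chrom_lengths`,
#'   `fragments`, `sample_table`, `samples` (named list of CGmap tibbles)
#'   and `truth` (list with `dm_sites`, `dm_site_comparisons`,
#'   `dm_regions`).
#' @export
simulate_methylome <- function(config = sim_config(), outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  gen <- generate_genome(config)
  fragments <- purrr::imap(gen$genome, function(s, ch) {
    fr <- msp1_digest(s, config$frag_min, config$frag_max)
    dplyr::mutate(fr, chrom = ch, .before = 1)
  }) |> dplyr::bind_rows()

  sites <- purrr::imap(gen$genome, function(s, ch) {
    enumerate_sites(strsplit(s, "", fixed = TRUE)[[1]],
                    fragments[fragments$chrom == ch, , drop = FALSE], chrom = ch)
  }) |> dplyr::bind_rows()

  # plant comparison-specific DM sites: each planted site is shifted in one
  # target stage, so it is truly differential exactly for the two
  # comparisons involving that stage
  set.seed(derive_seed(config$seed, 2))
  in_island <- sites_in_intervals(sites$chrom, sites$pos, gen$cgis)
  base_p <- ifelse(sites$context == "CpG",
                   ifelse(in_island, config$cpg_level_island, config$cpg_level_open),
                   config$cph_level)
  dm_plan <- list()
  for (ctx in c("CpG", "CpH")) {
    ix <- which(sites$context == ctx)
    n_dm <- floor(config$dm_site_fraction * length(ix))
    if (n_dm == 0) next
    pick <- sort(sample(ix, n_dm))
    eff <- ifelse(base_p[pick] + config$dm_effect <= 0.98,
                  config$dm_effect, -config$dm_effect)
    dm_plan[[ctx]] <- tibble::tibble(
      chrom = sites$chrom[pick], pos = sites$pos[pick],
      strand = sites$strand[pick], context = ctx,
      target_stage = sample(STAGES, n_dm, replace = TRUE),
      effect = eff)
  }
  dm_sites <- dplyr::bind_rows(dm_plan)

  dm_regions <- NULL
  if (config$dm_region_count > 0) {
    n_isl <- min(ceiling(config$dm_region_count / 2), nrow(gen$cgis))
    n_gen <- min(config$dm_region_count - n_isl, nrow(gen$genes))
    isl_pick <- gen$cgis[sample.int(nrow(gen$cgis), n_isl), ]
    gene_pick <- gen$genes[sample.int(nrow(gen$genes), n_gen), ]
    dm_regions <- dplyr::bind_rows(
      tibble::tibble(region_id = isl_pick$name, kind = "CGI",
                     chrom = isl_pick$chrom, start = isl_pick$start,
                     end = isl_pick$end, effect = config$dm_region_effect),
      tibble::tibble(region_id = gene_pick$gene_id, kind = "gene",
                     chrom = gene_pick$chrom, start = gene_pick$start - 5000,
                     end = gene_pick$end + 5000, effect = -config$dm_region_effect)
    )
    dm_regions$target_stage <- sample(STAGES, nrow(dm_regions), replace = TRUE)
  }

  # per-comparison site truth: expected pooled delta (stage A minus stage B)
  comparisons <- tibble::tibble(
    comparison = c("PreVsIn", "InVsPost", "PreVsPost"),
    a = c("Pre", "In", "Pre"), b = c("In", "Post", "Post"))
  truth_cmp <- purrr::pmap(comparisons, function(comparison, a, b) {
    if (is.null(dm_sites) || !nrow(dm_sites)) return(NULL)
    d <- dm_sites$effect * ((dm_sites$target_stage == a) - (dm_sites$target_stage == b))
    keep <- d != 0
    tibble::tibble(comparison = comparison,
                   chrom = dm_sites$chrom[keep], pos = dm_sites$pos[keep],
                   strand = dm_sites$strand[keep], context = dm_sites$context[keep],
                   expected_delta = d[keep])
  }) |> dplyr::bind_rows()

  sample_table <- tidyr::expand_grid(stage = factor(STAGES, levels = STAGES),
                                     replicate = 1:3) |>
    dplyr::mutate(stage = as.character(.data$stage),
                  sample = paste0(.data$stage, "_", .data$replicate)) |>
    dplyr::select("sample", "stage", "replicate")

  samples <- purrr::pmap(sample_table, function(sample, stage, replicate) {
    simulate_counts(gen$genome, fragments, config, stage, replicate,
                    islands = gen$cgis, dm_sites = dm_sites,
                    dm_regions = dm_regions, sites = sites)
  })
  names(samples) <- sample_table$sample

  res <- list(genome = gen$genome, genes = gen$genes, cgis = gen$cgis,
              qtls = gen$qtls, chrom_lengths = gen$chrom_lengths,
              fragments = fragments, sample_table = sample_table,
              samples = samples,
              truth = list(dm_sites = dm_sites,
                           dm_site_comparisons = truth_cmp,
                           dm_regions = dm_regions))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(res$genome, file.path(outdir, "genome.fa"))
    write_gene_bed12(res$genes, file.path(outdir, "genes.bed"))
    write_bed(res$qtls, file.path(outdir, "qtls.bed"))
    write_bed(res$cgis, file.path(outdir, "cgis_truth.bed"))
    readr::write_tsv(res$sample_table, file.path(outdir, "sample_table.tsv"), progress = FALSE)
    for (s in names(samples)) {
      write_cgmap(samples[[s]], file.path(outdir, paste0(s, ".cgmap.tsv")))
    }
    if (!is.null(dm_sites)) readr::write_tsv(dm_sites, file.path(outdir, "truth_dm_sites.tsv"), progress = FALSE)
    if (!is.null(truth_cmp)) readr::write_tsv(truth_cmp, file.path(outdir, "truth_dm_site_comparisons.tsv"), progress = FALSE)
    if (!is.null(dm_regions)) readr::write_tsv(dm_regions, file.path(outdir, "truth_dm_regions.tsv"), progress = FALSE)
  }
  res
}
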