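COMPARISONS <- tibble::tibble(
  comparison = c("PreVsIn", "InVsPost", "PreVsPost"),
  a = c("Pre", "In", "Pre"),
  b = c("In", "Post", "Post"))

resolve_comparison <- function(comparison) {
  if (is.character(comparison) && length(comparison) == 1) {
    i <- match(comparison, COMPARISONS$comparison)
    if (is.na(i)) rlang::abort("unknown comparison name")
    return(list(name = comparison, a = COMPARISONS$a[i], b = COMPARISONS$b[i]))
  }
  if (length(comparison) == 2) {
    check_stage(comparison)
    if (comparison[1] == comparison[2]) rlang::abort("the two groups must differ")
    return(list(name = paste0(comparison[1], "Vs", comparison[2]),
                a = comparison[1], b = comparison[2]))
  }
  rlang::abort("comparison must be a name or a pair of stages")
}

#' Two-tail Fisher exact test probability for 2x2 tables
#'
#' Computes, for each table `[[a, b], [c, d]]` with fixed margins, the
#' two-sided p-value as the sum of hypergeometric probabilities of all
#' tables whose probability does not exceed that of the observed table.
#' Vectorised over tables; an empty margin gives p = 1 by convention.
#'
#' @param a,b,c,d Non-negative integer count vectors (recycled).
#' @return Numeric vector of two-sided p-values.
#' @export
#' @examples
#' fisher_exact_two_tail(20, 0, 0, 20)
fisher_exact_two_tail <- function(a, b, c, d) {
  nn <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), nn); b <- rep_len(as.numeric(b), nn)
  c <- rep_len(as.numeric(c), nn); d <- rep_len(as.numeric(d), nn)
  if (any(c(a, b, c, d) < 0)) rlang::abort("counts must be non-negative")
  # identical tables are frequent in per-site testing: test each once
  key <- paste(a, b, c, d)
  u <- !duplicated(key)
  pu <- vapply(which(u), function(i) {
    m1 <- a[i] + b[i]; m2 <- c[i] + d[i]; k <- a[i] + c[i]
    if (m1 == 0 || m2 == 0 || k == 0 || k == m1 + m2) return(1)
    supp <- max(0, k - m2):min(k, m1)
    probs <- stats::dhyper(supp, m1, m2, k)
    p_obs <- probs[supp == a[i]]
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }, numeric(1))
  unname(pmin(pu[match(key, key[u])], 1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment:
#' `q(i) = min over j with rank >= rank(i) of m * p(j) / rank(j)`, capped
#' at 1.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of adjusted values, in the input order.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1)) rlang::abort("p must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially methylated sites (DMCs / DMHs)
#'
#' For each retained site, reads are pooled across the replicates of each
#' group and tested with the two-tail Fisher exact test on the 2x2 table of
#' methylated/unmethylated read counts. The methylation difference `delta`
#' is the pooled level of group A minus that of group B. P-values are
#' FDR-adjusted (Benjamini-Hochberg) separately within each context of the
#' comparison, and a site is differentially methylated when `q <= q_max`
#' and `|delta| > delta_min` (strictly more than a 20% change by default).
#' Differentially methylated CpG sites are DMCs, CpH sites DMHs; polarity
#' marks the group with the higher level as hyper-methylated.
#'
#' @param x A `site_matrix` from [load_and_filter()].
#' @param comparison A comparison name (`"PreVsIn"`, `"InVsPost"`,
#'   `"PreVsPost"`) or a length-2 vector of stages `c(A, B)`.
#' @param delta_min Strict lower bound on `|delta|` (default 0.20).
#' @param q_max Inclusive FDR threshold (default 0.05).
#' @return A `dm_sites` tibble: site columns, `comparison`, `level_a`,
#'   `level_b`, `delta`, `p`, `q`, `is_dm`, `polarity`
#'   (`hyper_in_a` / `hyper_in_b` / `none`).
#' @export
dm_site_test <- function(x, comparison, delta_min = 0.20, q_max = 0.05) {
  cmp <- resolve_comparison(comparison)
  st <- sample_table(x)
  sa <- st$sample[st$stage == cmp$a]
  sb <- st$sample[st$stage == cmp$b]
  if (!length(sa) || !length(sb)) rlang::abort("comparison stage missing from the sample table")
  ma <- rowSums(sm_matrix(x, "meth", sa)); ta <- rowSums(sm_matrix(x, "total", sa))
  mb <- rowSums(sm_matrix(x, "meth", sb)); tb <- rowSums(sm_matrix(x, "total", sb))
  if (any(ta == 0) || any(tb == 0)) rlang::abort("site with no coverage in a group; matrix was not filtered")
  level_a <- ma / ta
  level_b <- mb / tb
  delta <- level_a - level_b
  p <- fisher_exact_two_tail(ma, ta - ma, mb, tb - mb)
  out <- tibble::tibble(
    chrom = x$chrom, pos = x$pos, strand = x$strand, context = x$context,
    comparison = cmp$name,
    level_a = level_a, level_b = level_b, delta = delta, p = p)
  out <- dplyr::mutate(dplyr::group_by(out, .data$context),
                       q = bh_fdr(.data$p)) |> dplyr::ungroup()
  out$is_dm <- out$q <= q_max & abs(out$delta) > delta_min
  out$polarity <- ifelse(!out$is_dm, "none",
                         ifelse(out$delta > 0, "hyper_in_a", "hyper_in_b"))
  attr(out, "comparison") <- cmp
  attr(out, "thresholds") <- c(delta_min = delta_min, q_max = q_max)
  class(out) <- c("dm_sites", class(tibble::tibble()))
  out
}

# classical pooled-variance two-sample t; returns two-sided p.
# Zero pooled variance: p = 1 for equal means, p = 0 (flagged upstream)
# otherwise.
student_t_p <- function(xa, xb, var_equal = TRUE) {
  na <- length(xa); nb <- length(xb)
  ma <- mean(xa); mb <- mean(xb)
  va <- stats::var(xa); vb <- stats::var(xb)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 == 0) return(if (ma == mb) 1 else 0)
    t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se2 <- va / na + vb / nb
    if (se2 == 0) return(if (ma == mb) 1 else 0)
    t <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  2 * stats::pt(-abs(t), df)
}

#' Call differentially methylated regions (DMIs / DMGs)
#'
#' For each region covered by at least `min_sites` sites of the tested
#' context, the per-replicate region mean (average of that replicate's
#' site levels inside the region) is computed for both groups and compared
#' with a two-tailed Student's t-test (pooled variance; Welch available via
#' `var_equal = FALSE`). P-values are FDR-adjusted across the tested
#' regions of the call, and a region is differentially methylated when
#' `q <= q_max`. Islands tested this way are DMIs; gene bodies extended by
#' 5 kb flanks are DMGs.
#'
#' @param regions Interval tibble (`chrom`, `start`, `end`) with optional
#'   `region_id` and `kind` columns.
#' @param x A `site_matrix`.
#' @param comparison As in [dm_site_test()].
#' @param context `"CpG"` or `"CpH"`.
#' @param min_sites Minimum covered sites for a region to be tested
#'   (default 20).
#' @param q_max Inclusive FDR threshold (default 0.05).
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @return A `dm_regions` tibble: `region_id`, `kind`, `chrom`, `start`,
#'   `end`, `context`, `comparison`, `n_sites`, `mean_a`, `mean_b`, `p`,
#'   `q`, `is_dm`, `tested`, `zero_variance`.
#' @export
dm_region_test <- function(regions, x, comparison, context = "CpG",
                           min_sites = 20, q_max = 0.05, var_equal = TRUE) {
  cmp <- resolve_comparison(comparison)
  check_intervals(regions, "regions")
  st <- sample_table(x)
  sa <- st$sample[st$stage == cmp$a]
  sb <- st$sample[st$stage == cmp$b]
  sub <- x[x$context == context, , drop = FALSE]
  lev <- sm_matrix(sub, "meth", c(sa, sb)) / sm_matrix(sub, "total", c(sa, sb))
  lev_tbl <- tibble::as_tibble(lev)
  names(lev_tbl) <- c(sa, sb)
  lev_tbl$chrom <- sub$chrom; lev_tbl$pos <- sub$pos
  idx <- chrom_index(lev_tbl, c(sa, sb))

  n <- nrow(regions)
  out <- tibble::tibble(
    region_id = if ("region_id" %in% names(regions)) regions$region_id else
      if ("name" %in% names(regions)) regions$name else
        if ("gene_id" %in% names(regions)) regions$gene_id else
          sprintf("region%05d", seq_len(n)),
    kind = if ("kind" %in% names(regions)) regions$kind else "region",
    chrom = regions$chrom, start = regions$start, end = regions$end,
    context = context, comparison = cmp$name,
    n_sites = 0L, mean_a = NA_real_, mean_b = NA_real_,
    p = NA_real_, q = NA_real_, is_dm = FALSE, tested = FALSE,
    zero_variance = FALSE)

  for (i in seq_len(n)) {
    ci <- idx[[regions$chrom[i]]]
    if (is.null(ci)) next
    i1 <- findInterval(regions$start[i] - 0.5, ci$pos0) + 1L
    i2 <- findInterval(regions$end[i] - 0.5, ci$pos0)
    if (i2 < i1) next
    out$n_sites[i] <- i2 - i1 + 1L
    rep_means <- vapply(c(sa, sb), function(s) {
      (ci$cums[[s]][i2 + 1] - ci$cums[[s]][i1]) / (i2 - i1 + 1L)
    }, numeric(1))
    xa <- rep_means[seq_along(sa)]
    xb <- rep_means[length(sa) + seq_along(sb)]
    out$mean_a[i] <- mean(xa); out$mean_b[i] <- mean(xb)
    if (out$n_sites[i] >= min_sites) {
      out$tested[i] <- TRUE
      out$p[i] <- student_t_p(xa, xb, var_equal = var_equal)
      out$zero_variance[i] <- stats::var(xa) == 0 && stats::var(xb) == 0
    }
  }
  out$q[out$tested] <- bh_fdr(out$p[out$tested])
  out$is_dm <- !is.na(out$q) & out$q <= q_max
  if (any(out$zero_variance & out$tested & out$p == 0)) {
    rlang::warn("regions with zero replicate variance and unequal means: p set to 0")
  }
  attr(out, "comparison") <- cmp
  class(out) <- c("dm_regions", class(tibble::tibble()))
  out
}

#' Genes containing at least one differentially methylated site
#'
#' A gene "regarding" DM sites is one whose extended span (body plus 5 kb
#' flanks on both sides) contains at least one DMC (or DMH).
#'
#' @param dm A `dm_sites` result (only rows with `is_dm` are used) or any
#'   tibble of sites (`chrom`, `pos`).
#' @param genes Gene-model tibble.
#' @param flank Flank width in bp (default 5000).
#' @return Character vector of gene ids, sorted.
#' @export
dm_regarding_genes <- function(dm, genes, flank = 5000) {
  if ("is_dm" %in% names(dm)) dm <- dm[dm$is_dm, , drop = FALSE]
  if (!nrow(dm)) return(character(0))
  pairs <- genes_for_site(dm[, c("chrom", "pos")], genes, flank = flank)
  sort(unique(pairs$gene_id))
}

#' Genes whose extended span overlaps a differentially methylated island
#'
#' @param dmis A `dm_regions` result for islands (rows with `is_dm` are
#'   used) or an interval tibble of DMI intervals.
#' @param genes Gene-model tibble.
#' @param flank Flank width in bp (default 5000).
#' @return Character vector of gene ids, sorted.
#' @export
dmi_regarding_genes <- function(dmis, genes, flank = 5000) {
  if ("is_dm" %in% names(dmis)) dmis <- dmis[dmis$is_dm, , drop = FALSE]
  if (!nrow(dmis)) return(character(0))
  spans <- new_intervals(genes$chrom, genes$start - flank, genes$end + flank)
  hits <- overlap_pairs(spans, dmis[, c("chrom", "start", "end")])
  sort(unique(genes$gene_id[hits$i]))
}
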