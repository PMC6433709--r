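#' Build the filtered multi-sample site matrix
#'
#' Retains exactly the sites that are present, with coverage of at least
#' `min_cov` reads, in every sample ("covered by at least five reads and
#' co-existing across all samples"). Strands are never merged: the two
#' cytosines of a CpG dinucleotide are distinct sites.
#'
#' @param samples Named list of CGmap-style tibbles (as returned by
#'   [read_cgmap()] or [simulate_counts()]) or a named character vector of
#'   file paths.
#' @param sample_table Tibble with columns `sample`, `stage`
#'   (`Pre`/`In`/`Post`) and `replicate`. When `NULL`, stages are parsed
#'   from sample names of the form `<stage>_<replicate>`.
#' @param min_cov Minimum per-sample coverage (default 5).
#' @return A `site_matrix`: a tibble with one row per retained site
#'   (`chrom`, `pos`, `strand`, `context`) and two columns per sample
#'   (`meth_<sample>`, `total_<sample>`), carrying the sample table as an
#'   attribute.
#' @export
load_and_filter <- function(samples, sample_table = NULL, min_cov = 5) {
  if (is.character(samples)) {
    paths <- samples
    samples <- purrr::map(paths, read_cgmap)
    names(samples) <- names(paths) %||% sub("\\.cgmap.*$", "", basename(paths))
  } else {
    samples <- purrr::imap(samples, function(x, nm) {
      if (all(c("strand", "context") %in% names(x))) x else normalize_cgmap(x, nm)
    })
  }
  if (length(samples) < 2) rlang::abort("need at least two samples")
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    rlang::abort("samples must be named")
  }
  if (is.null(sample_table)) {
    parts <- strsplit(names(samples), "_", fixed = TRUE)
    sample_table <- tibble::tibble(
      sample = names(samples),
      stage = purrr::map_chr(parts, 1),
      replicate = as.integer(purrr::map_chr(parts, 2)))
  }
  check_stage(sample_table$stage)
  if (!setequal(sample_table$sample, names(samples))) {
    rlang::abort("sample_table does not match the sample names")
  }

  n <- length(samples)
  long <- dplyr::bind_rows(samples, .id = "sample")
  long <- long[, c("sample", "chrom", "pos", "strand", "context", "meth", "total")]
  key <- paste(long$chrom, long$pos)
  passing <- long$total >= min_cov
  tab <- rowsum(as.integer(passing), key)
  keep_keys <- rownames(tab)[tab[, 1] == n]
  long <- long[key %in% keep_keys, , drop = FALSE]

  wide <- tidyr::pivot_wider(long,
                             id_cols = c("chrom", "pos", "strand", "context"),
                             names_from = "sample",
                             values_from = c("meth", "total"))
  wide <- dplyr::arrange(wide, .data$chrom, .data$pos)
  # guard against a site present twice in one file (pivot would make lists)
  if (any(purrr::map_lgl(wide, is.list))) {
    rlang::abort("duplicate site within a sample")
  }
  new_site_matrix(wide, sample_table)
}

new_site_matrix <- function(x, sample_table) {
  structure(x, class = c("site_matrix", class(tibble::tibble()))) |>
    (\(y) { attr(y, "sample_table") <- sample_table; y })()
}

#' Sample table of a site matrix
#' @param x A `site_matrix`.
#' @return The sample tibble (`sample`, `stage`, `replicate`).
#' @export
sample_table <- function(x) attr(x, "sample_table")

sm_matrix <- function(x, what = c("meth", "total"), samples = NULL) {
  what <- match.arg(what)
  st <- sample_table(x)
  samples <- samples %||% st$sample
  as.matrix(x[, paste0(what, "_", samples), drop = FALSE])
}

#' Per-site methylation level
#'
#' The methylation level of a site is the number of methylated reads
#' divided by the total covered reads.
#'
#' @param meth,total Count vectors, `0 <= meth <= total`, `total > 0`.
#' @return Numeric vector of levels in `[0, 1]`.
#' @export
site_level <- function(meth, total) {
  if (any(total <= 0)) rlang::abort("site_level undefined for total <= 0")
  if (any(meth < 0 | meth > total)) rlang::abort("need 0 <= meth <= total")
  meth / total
}

#' Group (stage) methylation level per site
#'
#' The stage-level methylation of a site is the unweighted mean of the
#' replicate site levels (not the pooled-read ratio; pooling is used only
#' inside the site-level Fisher test).
#'
#' @param x A `site_matrix`.
#' @param stages Stages to compute (default all present).
#' @return Tibble with the site columns plus one level column per stage.
#' @export
group_levels <- function(x, stages = NULL) {
  st <- sample_table(x)
  stages <- stages %||% unique(st$stage)
  out <- x[, c("chrom", "pos", "strand", "context")]
  for (s in stages) {
    sm <- st$sample[st$stage == s]
    lev <- sm_matrix(x, "meth", sm) / sm_matrix(x, "total", sm)
    out[[s]] <- rowMeans(lev)
  }
  tibble::as_tibble(out)
}

# sorted positions + cumulative level sums per chromosome, for fast
# region aggregation
chrom_index <- function(levels_tbl, value_cols) {
  split(levels_tbl, levels_tbl$chrom) |>
    purrr::map(function(d) {
      d <- d[order(d$pos), , drop = FALSE]
      list(pos0 = d$pos - 1, d = d,
           cums = purrr::map(value_cols, ~ c(0, cumsum(d[[.x]]))) |>
             stats::setNames(value_cols))
    })
}

#' Mean methylation level of regions
#'
#' The methylation level of a region is the average of the stage-level
#' values of the sites of the requested context inside it.
#'
#' @param regions Interval tibble (`chrom`, `start`, `end`), 0-based
#'   half-open; extra columns are preserved.
#' @param x A `site_matrix`.
#' @param context `"CpG"` or `"CpH"`.
#' @param stages Stages to report (default all).
#' @return `regions` with added `n_sites` and one mean-level column per
#'   stage (`NA` when `n_sites` is 0).
#' @export
region_level <- function(regions, x, context = "CpG", stages = NULL) {
  check_intervals(regions, "regions")
  st <- sample_table(x)
  stages <- stages %||% unique(st$stage)
  gl <- group_levels(x, stages)
  gl <- gl[gl$context == context, , drop = FALSE]
  idx <- chrom_index(gl, stages)
  n_sites <- integer(nrow(regions))
  means <- matrix(NA_real_, nrow(regions), length(stages),
                  dimnames = list(NULL, stages))
  for (i in seq_len(nrow(regions))) {
    ci <- idx[[regions$chrom[i]]]
    if (is.null(ci)) next
    i1 <- findInterval(regions$start[i] - 0.5, ci$pos0) + 1L
    i2 <- findInterval(regions$end[i] - 0.5, ci$pos0)
    if (i2 < i1) next
    n_sites[i] <- i2 - i1 + 1L
    for (s in stages) {
      means[i, s] <- (ci$cums[[s]][i2 + 1] - ci$cums[[s]][i1]) / n_sites[i]
    }
  }
  out <- tibble::as_tibble(regions)
  out$n_sites <- n_sites
  for (s in stages) out[[s]] <- means[, s]
  out
}

#' Binned methylation profile over genes or CpG islands
#'
#' Gene scheme: 20 fixed-width bins over the 5 kb upstream flank, 40
#' length-proportional bins over the body, 20 over the 5 kb downstream
#' flank. CGI scheme: 20/20/20 bins with 2 kb flanks. Bin 1 is always the
#' 5'-most bin: minus-strand genes are orientation-flipped. A site exactly
#' on a bin boundary goes to the lower bin. Regions shorter than the number
#' of body bins are skipped with a warning; sites contribute to every
#' region whose span they fall in.
#'
#' @param regions For `scheme = "gene"` a gene-model tibble (strand used);
#'   for `scheme = "cgi"` an island interval tibble (unstranded).
#' @param x A `site_matrix`.
#' @param scheme `"gene"` (20/40/20, 5 kb flanks) or `"cgi"` (20/20/20,
#'   2 kb flanks).
#' @param context `"CpG"` or `"CpH"`.
#' @param stages Stages to profile (default all).
#' @return Tibble with `bin`, `zone` (upstream/body/downstream), `stage`,
#'   `mean_level`, `n_sites`.
#' @export
binned_profile <- function(regions, x, scheme = c("gene", "cgi"),
                           context = "CpG", stages = NULL) {
  scheme <- match.arg(scheme)
  flank <- if (scheme == "gene") 5000 else 2000
  n_up <- 20L
  n_body <- if (scheme == "gene") 40L else 20L
  n_down <- 20L
  st <- sample_table(x)
  stages <- stages %||% unique(st$stage)
  gl <- group_levels(x, stages)
  gl <- gl[gl$context == context, , drop = FALSE]
  idx <- chrom_index(gl, stages)

  strand <- if ("strand" %in% names(regions)) regions$strand else rep("+", nrow(regions))
  short <- (regions$end - regions$start) < n_body
  if (any(short)) {
    rlang::warn(sprintf("%d regions shorter than %d bp skipped", sum(short), n_body))
  }

  assign_bins <- function(i) {
    ci <- idx[[regions$chrom[i]]]
    if (is.null(ci)) return(NULL)
    s <- regions$start[i]; e <- regions$end[i]; len <- e - s
    i1 <- findInterval(s - flank - 0.5, ci$pos0) + 1L
    i2 <- findInterval(e + flank - 0.5, ci$pos0)
    if (i2 < i1) return(NULL)
    sel <- i1:i2
    p0 <- ci$pos0[sel]
    if (strand[i] == "+") {
      d_up <- p0 - (s - flank) + 1          # 1..flank within upstream flank
      d_body <- p0 - s + 1                  # 1..len within body
      d_down <- p0 - e + 1                  # 1..flank within downstream flank
    } else {
      d_up <- (e + flank) - p0              # distance from 5' end on minus
      d_body <- e - p0
      d_down <- s - p0
    }
    bin <- ifelse(d_body >= 1 & d_body <= len,
                  n_up + ceiling(d_body * n_body / len),
                  ifelse(d_up >= 1 & d_up <= flank,
                         ceiling(d_up * n_up / flank),
                         n_up + n_body + ceiling(d_down * n_down / flank)))
    tibble::tibble(bin = as.integer(bin), site = sel, region = i)
  }

  pairs <- purrr::map(which(!short), assign_bins) |> dplyr::bind_rows()
  grid <- tidyr::expand_grid(bin = seq_len(n_up + n_body + n_down),
                             stage = stages)
  if (!nrow(pairs)) {
    out <- dplyr::mutate(grid, mean_level = NA_real_, n_sites = 0L)
  } else {
    pair_chrom <- regions$chrom[pairs$region]
    long <- purrr::map(stages, function(s) {
      lev <- numeric(nrow(pairs))
      for (ch in unique(pair_chrom)) {
        ii <- pair_chrom == ch
        lev[ii] <- idx[[ch]]$d[[s]][pairs$site[ii]]
      }
      tibble::tibble(bin = pairs$bin, stage = s, level = lev)
    }) |> dplyr::bind_rows()
    agg <- dplyr::summarise(dplyr::group_by(long, .data$bin, .data$stage),
                            mean_level = mean(.data$level),
                            n_sites = dplyr::n(), .groups = "drop")
    out <- dplyr::left_join(grid, agg, by = c("bin", "stage"))
    out$n_sites[is.na(out$n_sites)] <- 0L
  }
  out$zone <- dplyr::case_when(
    out$bin <= n_up ~ "upstream",
    out$bin <= n_up + n_body ~ "body",
    TRUE ~ "downstream")
  dplyr::select(out, "bin", "zone", "stage", "mean_level", "n_sites")
}

#' Quantify sites or intervals per tiled genomic window
#'
#' Counts items (or averages site values) in non-overlapping windows tiled
#' from position 0, the quantification behind megabase-scale genome
#' tracks. Intervals are assigned to the window of their midpoint.
#'
#' @param items Tibble of sites (`chrom`, `pos`) or intervals (`chrom`,
#'   `start`, `end`).
#' @param chrom_lengths Named numeric vector of chromosome lengths; the
#'   window grid covers every chromosome fully and is identical across
#'   tracks of the same genome.
#' @param width Window width in bp (default 1e6).
#' @param mode `"density"` (count per window) or `"mean_level"` (mean of
#'   `value` over sites in the window).
#' @param value For `mode = "mean_level"`, the name of the value column.
#' @return Tibble with `chrom`, `win_start`, `win_end`, `value` for every
#'   window in the grid (0 for empty windows in density mode, `NA` in
#'   mean-level mode).
#' @export
window_track <- function(items, chrom_lengths, width = 1e6,
                         mode = c("density", "mean_level"), value = "level") {
  mode <- match.arg(mode)
  if (width <= 0) rlang::abort("width must be positive")
  grid <- purrr::imap(chrom_lengths, function(L, ch) {
    ws <- seq(0, L - 1e-9, by = width)
    tibble::tibble(chrom = ch, win_start = ws, win_end = pmin(ws + width, L))
  }) |> dplyr::bind_rows()
  if (nrow(items) == 0) {
    grid$value <- if (mode == "density") 0 else NA_real_
    return(grid)
  }
  p0 <- if ("pos" %in% names(items)) items$pos - 1 else floor((items$start + items$end) / 2)
  win <- floor(p0 / width) * width
  key <- paste(items$chrom, win)
  gkey <- paste(grid$chrom, grid$win_start)
  if (mode == "density") {
    cnt <- table(key)
    grid$value <- as.numeric(cnt[gkey])
    grid$value[is.na(grid$value)] <- 0
  } else {
    v <- items[[value]]
    agg <- tapply(v, key, mean)
    grid$value <- as.numeric(agg[gkey])
  }
  grid
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y Numeric vectors of equal length (at least 3 finite pairs).
#' @return Tibble with `r`, `p`, `n`. When either vector has zero
#'   variance, `r` and `p` are `NA` and a warning is raised.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) rlang::abort("need at least 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::warn("zero variance: correlation undefined")
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
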