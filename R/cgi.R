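#' Composition scores of a sequence segment
#'
#' Computes the quantities entering the classic CpG-island criteria:
#' GC fraction, observed CpG dinucleotide count, expected CpG count
#' (number of C times number of G divided by segment length) and their
#' observed/expected ratio. `N` bases count toward the length but not
#' toward the composition, and a `CG` pair interrupted by `N` does not
#' count as observed.
#'
#' @param segment Character vector of uppercase `ACGTN` sequences.
#' @return Tibble with one row per segment: `length`, `gc_fraction`,
#'   `obs_cpg`, `exp_cpg`, `oe_ratio` (0 when `exp_cpg` is 0).
#' @export
#' @examples
#' score_segment(strrep("CG", 150))
score_segment <- function(segment) {
  if (!is.character(segment) || any(is.na(segment)) || any(nchar(segment) == 0)) {
    rlang::abort("segment must be non-empty character strings")
  }
  if (any(grepl("[^ACGTN]", segment))) {
    rlang::abort("segment contains symbols outside the ACGTN alphabet")
  }
  len <- nchar(segment)
  n_c <- stringr::str_count(segment, stringr::fixed("C"))
  n_g <- stringr::str_count(segment, stringr::fixed("G"))
  obs <- stringr::str_count(segment, stringr::fixed("CG"))
  exp_cpg <- n_c * n_g / len
  tibble::tibble(
    length = len,
    gc_fraction = (n_c + n_g) / len,
    obs_cpg = obs,
    exp_cpg = exp_cpg,
    oe_ratio = ifelse(exp_cpg > 0, obs / exp_cpg, 0)
  )
}

# cumulative composition arrays for O(1) scoring of any sub-segment
seg_cums <- function(chars) {
  n <- length(chars)
  cg_start <- if (n > 1) (chars[-n] == "C" & chars[-1] == "G") else logical(0)
  list(
    n = n,
    C = c(0, cumsum(chars == "C")),
    G = c(0, cumsum(chars == "G")),
    CG = c(0, cumsum(c(cg_start, FALSE)))
  )
}

# vectorised scores of [a, b) (0-based half-open, local coordinates)
seg_stats <- function(cums, a, b) {
  len <- b - a
  n_c <- cums$C[b + 1] - cums$C[a + 1]
  n_g <- cums$G[b + 1] - cums$G[a + 1]
  # CG pairs fully inside: starts at local 1-based positions (a+1)..(b-1)
  obs <- cums$CG[b] - cums$CG[a + 1]
  exp_cpg <- n_c * n_g / len
  list(len = len, gc = (n_c + n_g) / len, obs = obs, exp = exp_cpg,
       oe = ifelse(exp_cpg > 0, obs / exp_cpg, 0))
}

seg_ok <- function(cums, a, b, min_length, min_gc, min_oe) {
  st <- seg_stats(cums, a, b)
  st$len >= min_length & st$gc > min_gc & st$oe > min_oe
}

# longest-leftmost selection of non-overlapping qualifying sub-segments of
# [lo, hi): take the longest qualifying sub-segment (leftmost on ties),
# then recurse into the two flanks.
select_islands <- function(cums, lo, hi, min_length, min_gc, min_oe) {
  if (hi - lo < min_length) return(NULL)
  for (len in seq(hi - lo, min_length)) {
    a <- lo:(hi - len)
    ok <- seg_ok(cums, a, a + len, min_length, min_gc, min_oe)
    if (any(ok)) {
      a0 <- a[which(ok)[1]]
      return(rbind(
        select_islands(cums, lo, a0, min_length, min_gc, min_oe),
        c(a0, a0 + len),
        select_islands(cums, a0 + len, hi, min_length, min_gc, min_oe)
      ))
    }
  }
  NULL
}

# greedy end-trimming fallback for very long candidate regions: shrink the
# end whose removal best improves the failing criteria
trim_greedy <- function(cums, a, b, min_length, min_gc, min_oe) {
  while (b - a >= min_length) {
    if (seg_ok(cums, a, b, min_length, min_gc, min_oe)) return(c(a, b))
    score <- function(x, y) {
      st <- seg_stats(cums, x, y)
      min(st$gc - min_gc, st$oe - min_oe)
    }
    if (score(a + 1, b) >= score(a, b - 1)) a <- a + 1 else b <- b - 1
  }
  NULL
}

#' Call CpG islands on a sequence
#'
#' Detects islands by the UCSC-style criteria: length greater than 200 bp,
#' GC fraction greater than 0.5 and observed/expected CpG ratio greater
#' than 0.6 (all strict). Runs of `N` split the sequence; no island spans
#' an N gap. On short N-free blocks (up to `exhaustive_limit` bases) the
#' caller selects, exhaustively and recursively, the longest (leftmost on
#' ties) non-overlapping qualifying sub-segments. On longer blocks it first
#' screens with 200-bp sliding windows passing the GC and O/E criteria,
#' merges overlapping windows into candidate regions, and applies the same
#' exhaustive selection inside each candidate.
#'
#' @param sequence A single uppercase `ACGTN` string.
#' @param chrom Chromosome name used in the output.
#' @param min_length Minimum island length in bp (default 201, i.e. > 200).
#' @param min_gc Strict lower bound on GC fraction (default 0.5).
#' @param min_oe Strict lower bound on observed/expected CpG (default 0.6).
#' @param window Screening window size in bp (default 200).
#' @param exhaustive_limit Block length up to which selection is exhaustive
#'   over all sub-segments (default 5000 bp).
#' @return Tibble of island records sorted by start: `chrom`, `start`,
#'   `end` (0-based half-open), `length`, `gc_fraction`, `obs_cpg`,
#'   `exp_cpg`, `oe_ratio`.
#' @export
call_cgis <- function(sequence, chrom = "chr1", min_length = 201L,
                      min_gc = 0.5, min_oe = 0.6, window = 200L,
                      exhaustive_limit = 5000L) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0) {
    rlang::abort("sequence must be a single non-empty string")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (any(!chars %in% c("A", "C", "G", "T", "N"))) {
    rlang::abort("sequence contains symbols outside the ACGTN alphabet")
  }
  isn <- chars == "N"
  r <- rle(isn)
  block_end <- cumsum(r$lengths)
  block_start <- block_end - r$lengths       # 0-based half-open blocks
  blocks <- which(!r$values & r$lengths >= min_length)

  found <- list()
  for (bi in blocks) {
    bs <- block_start[bi]; be <- block_end[bi]
    loc <- chars[(bs + 1):be]
    cums <- seg_cums(loc)
    n <- length(loc)
    if (n <= exhaustive_limit) {
      sel <- select_islands(cums, 0, n, min_length, min_gc, min_oe)
    } else {
      starts <- 0:(n - window)
      st <- seg_stats(cums, starts, starts + window)
      q <- which(st$gc > min_gc & st$oe > min_oe)
      sel <- NULL
      if (length(q)) {
        wiv <- merge_intervals(new_intervals("x", starts[q], starts[q] + window))
        for (k in seq_len(nrow(wiv))) {
          a <- wiv$start[k]; b <- wiv$end[k]
          piece <- if (b - a <= 10000) {
            select_islands(cums, a, b, min_length, min_gc, min_oe)
          } else {
            tg <- trim_greedy(cums, a, b, min_length, min_gc, min_oe)
            if (is.null(tg)) NULL else matrix(tg, ncol = 2)
          }
          sel <- rbind(sel, piece)
        }
      }
    }
    if (!is.null(sel) && nrow(sel)) {
      found[[length(found) + 1L]] <- tibble::tibble(start = bs + sel[, 1],
                                                    end = bs + sel[, 2])
    }
  }
  if (!length(found)) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                          length = numeric(), gc_fraction = numeric(),
                          obs_cpg = numeric(), exp_cpg = numeric(),
                          oe_ratio = numeric()))
  }
  iv <- dplyr::arrange(dplyr::bind_rows(found), .data$start)
  segs <- substring(sequence, iv$start + 1, iv$end)
  dplyr::bind_cols(tibble::tibble(chrom = chrom, start = iv$start, end = iv$end),
                   score_segment(segs))
}

#' Call CpG islands on a whole genome
#'
#' Applies [call_cgis()] to every sequence of a named set.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param ... Passed on to [call_cgis()].
#' @return Tibble of island records across chromosomes.
#' @export
call_cgis_genome <- function(genome, ...) {
  purrr::imap(genome, function(s, ch) call_cgis(s, chrom = ch, ...)) |>
    dplyr::bind_rows()
}

#' Derive CGI shores and shelves from island intervals
#'
#' Shores are the 2 kb flanks on either side of each island, shelves the
#' next 2 kb beyond the shores. Islands take precedence over shores and
#' shores over shelves, so the three classes are mutually disjoint even
#' when neighbouring islands are close; everything is clipped to the
#' chromosome bounds.
#'
#' @param islands Interval tibble (`chrom`, `start`, `end`), sorted and
#'   non-overlapping.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param flank Flank width in bp (default 2000).
#' @return An object of class `cgi_annotation`: a list with interval
#'   tibbles `islands`, `shores`, `shelves`.
#' @export
derive_shores_shelves <- function(islands, chrom_lengths, flank = 2000) {
  check_intervals(islands, "islands")
  islands <- dplyr::arrange(tibble::as_tibble(islands), .data$chrom, .data$start)
  if (nrow(islands) > 0) {
    if (!all(islands$chrom %in% names(chrom_lengths))) {
      rlang::abort("island chromosome absent from chrom_lengths")
    }
    if (any(islands$start < 0 | islands$end > chrom_lengths[islands$chrom])) {
      rlang::abort("island outside chromosome bounds")
    }
  }
  clip <- function(x) {
    x$start <- pmax(x$start, 0)
    x$end <- pmin(x$end, chrom_lengths[x$chrom])
    x[x$end > x$start, , drop = FALSE]
  }
  core <- islands[, c("chrom", "start", "end")]
  zone1 <- clip(new_intervals(core$chrom, core$start - flank, core$end + flank))
  zone2 <- clip(new_intervals(core$chrom, core$start - 2 * flank, core$end + 2 * flank))
  isl <- merge_intervals(core)
  shores <- subtract_intervals(merge_intervals(zone1), isl)
  shelves <- subtract_intervals(subtract_intervals(merge_intervals(zone2), merge_intervals(zone1)), isl)
  structure(list(islands = islands, shores = shores, shelves = shelves),
            class = "cgi_annotation")
}
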