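# Internal helpers shared across modules.
#
# Conventions used throughout the package:
#   * site positions are 1-based coordinates of the cytosine on the Watson
#     strand (a minus-strand cytosine is reported at the position of the G
#     it appears as on the Watson strand, as per-cytosine callers do);
#   * intervals are 0-based half-open tibbles with columns chrom, start, end
#     (BED convention), so a site at 1-based pos lies in [start, end) iff
#     start <= pos - 1 < end.

STAGES <- c("Pre", "In", "Post")

new_intervals <- function(chrom = character(), start = integer(), end = integer(), ...) {
  tibble::tibble(chrom = as.character(chrom), start = as.numeric(start),
                 end = as.numeric(end), ...)
}

check_intervals <- function(x, what = "intervals") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) {
    rlang::abort(paste0(what, " must have columns chrom, start, end"))
  }
  if (nrow(x) > 0 && any(x$end < x$start)) {
    rlang::abort(paste0(what, " contain end < start"))
  }
  invisible(x)
}

#' @keywords internal
merge_intervals <- function(x) {
  check_intervals(x)
  if (nrow(x) == 0) return(new_intervals())
  x <- dplyr::arrange(x[, c("chrom", "start", "end")], .data$chrom, .data$start, .data$end)
  dplyr::group_by(x, .data$chrom) |>
    dplyr::group_modify(function(d, key) {
      cme <- cummax(d$end)
      new_run <- c(TRUE, d$start[-1] > cme[-nrow(d)])
      g <- cumsum(new_run)
      tibble::tibble(
        start = as.numeric(tapply(d$start, g, min)),
        end   = as.numeric(tapply(d$end, g, max))
      )
    }) |>
    dplyr::ungroup()
}

# x minus y, per chromosome; both 0-based half-open
subtract_intervals <- function(x, y) {
  check_intervals(x); check_intervals(y)
  if (nrow(x) == 0) return(new_intervals())
  y <- merge_intervals(y)
  out <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    s <- x$start[i]; e <- x$end[i]; ch <- x$chrom[i]
    ys <- y[y$chrom == ch & y$end > s & y$start < e, , drop = FALSE]
    if (nrow(ys) == 0) {
      out[[i]] <- new_intervals(ch, s, e)
      next
    }
    pieces_s <- numeric(0); pieces_e <- numeric(0)
    cur <- s
    for (j in seq_len(nrow(ys))) {
      if (ys$start[j] > cur) {
        pieces_s <- c(pieces_s, cur); pieces_e <- c(pieces_e, ys$start[j])
      }
      cur <- max(cur, ys$end[j])
    }
    if (cur < e) { pieces_s <- c(pieces_s, cur); pieces_e <- c(pieces_e, e) }
    out[[i]] <- new_intervals(rep(ch, length(pieces_s)), pieces_s, pieces_e)
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$chrom, .data$start)
}

# logical: does each (chrom, pos [1-based]) fall inside any interval?
sites_in_intervals <- function(chrom, pos, intervals) {
  out <- logical(length(pos))
  if (is.null(intervals) || nrow(intervals) == 0) return(out)
  iv <- merge_intervals(intervals)
  for (ch in unique(chrom)) {
    sub <- iv[iv$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0) next
    ix <- which(chrom == ch)
    p0 <- pos[ix] - 1
    j <- findInterval(p0, sub$start)
    hit <- j > 0
    hit[hit] <- p0[hit] < sub$end[j[hit]]
    out[ix] <- hit
  }
  out
}

# interval pairs (i in x, j in y) overlapping by >= 1 bp
overlap_pairs <- function(x, y) {
  check_intervals(x); check_intervals(y)
  res <- list()
  for (ch in intersect(unique(x$chrom), unique(y$chrom))) {
    xi <- which(x$chrom == ch); yi <- which(y$chrom == ch)
    for (i in xi) {
      hit <- yi[y$start[yi] < x$end[i] & y$end[yi] > x$start[i]]
      if (length(hit)) res[[length(res) + 1L]] <- tibble::tibble(i = i, j = hit)
    }
  }
  if (!length(res)) return(tibble::tibble(i = integer(), j = integer()))
  dplyr::bind_rows(res)
}

# deterministic seed derivation that stays inside 32-bit integer range
derive_seed <- function(seed, ...) {
  ks <- c(...)
  as.integer((as.numeric(seed) + sum(as.numeric(ks) * 104729)) %% 2147483587)
}

# round-half-up, for report display (round() rounds half to even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

check_stage <- function(stage) {
  if (!all(stage %in% STAGES)) {
    rlang::abort(paste0("unknown stage; expected one of ", paste(STAGES, collapse = ", ")))
  }
  stage
}
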