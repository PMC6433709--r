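# Fixture builders shared across the suite. Everything is generated in
# code; seeds are fixed inside each test.

# a site_matrix from explicit per-site counts: counts is a list of
# site -> c(meth, total) per sample, or build from matrices
make_site_matrix <- function(meth, total, context = NULL, chrom = "chr1",
                             pos = NULL, strand = NULL,
                             stages = c("Pre", "In", "Post"), reps = 3) {
  meth <- as.matrix(meth); total <- as.matrix(total)
  n <- nrow(meth)
  samples <- paste0(rep(stages, each = reps), "_", rep(seq_len(reps), length(stages)))
  stopifnot(ncol(meth) == length(samples))
  x <- tibble::tibble(
    chrom = rep_len(chrom, n),
    pos = pos %||% seq(10, by = 10, length.out = n),
    strand = strand %||% rep("+", n),
    context = context %||% rep("CpG", n))
  for (j in seq_along(samples)) {
    x[[paste0("meth_", samples[j])]] <- meth[, j]
    x[[paste0("total_", samples[j])]] <- total[, j]
  }
  st <- tibble::tibble(sample = samples,
                       stage = rep(stages, each = reps),
                       replicate = rep(seq_len(reps), length(stages)))
  methylrrbs:::new_site_matrix(x, st)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random toy gene set on one chromosome, non-overlapping
toy_genes <- function(n = 3, chrom = "chr1", seed = 1) {
  set.seed(seed)
  start <- seq(20000, by = 30000, length.out = n)
  len <- sample(4000:9000, n, replace = TRUE)
  tibble::tibble(
    gene_id = paste0("g", seq_len(n)), chrom = chrom,
    strand = sample(c("+", "-"), n, replace = TRUE),
    start = start, end = start + len,
    exons = lapply(seq_len(n), function(i) {
      gs <- start[i]; ge <- start[i] + len[i]
      b <- sort(sample(seq(gs + 100, ge - 100, by = 50), 4))
      tibble::tibble(start = c(gs, b[2]), end = c(b[1], ge))
    }))
}

# independent per-base genic labelling oracle (direct definition scan)
oracle_genic_label <- function(chrom, pos, genes, flank = 5000) {
  p0 <- pos - 1
  lab <- "intergenic"
  for (cls in c("downstream", "upstream", "intron", "exon")) {
    for (i in seq_len(nrow(genes))) {
      if (genes$chrom[i] != chrom) next
      plus <- genes$strand[i] == "+"
      hit <- switch(cls,
        exon = any(p0 >= genes$exons[[i]]$start & p0 < genes$exons[[i]]$end),
        intron = p0 >= genes$start[i] && p0 < genes$end[i],
        upstream = if (plus) p0 >= genes$start[i] - flank && p0 < genes$start[i]
                   else p0 >= genes$end[i] && p0 < genes$end[i] + flank,
        downstream = if (plus) p0 >= genes$end[i] && p0 < genes$end[i] + flank
                     else p0 >= genes$start[i] - flank && p0 < genes$start[i])
      if (hit) { lab <- cls; break }
    }
  }
  lab
}

# brute-force segment scorer used as the independent CGI oracle: plain
# character counting, no cumulative sums
oracle_score <- function(seg) {
  ch <- strsplit(seg, "")[[1]]
  n_c <- sum(ch == "C"); n_g <- sum(ch == "G")
  obs <- sum(ch[-length(ch)] == "C" & ch[-1] == "G")
  len <- length(ch)
  expc <- n_c * n_g / len
  list(len = len, gc = (n_c + n_g) / len, obs = obs,
       oe = if (expc > 0) obs / expc else 0)
}

# exhaustive-substring island oracle: scores every substring of length
# min_len..nchar(seq), keeps qualifying ones, then iteratively selects the
# longest (leftmost on ties) non-overlapping ones
oracle_cgis <- function(seq, min_len = 201, min_gc = 0.5, min_oe = 0.6) {
  n <- nchar(seq)
  cand <- list()
  for (a in 0:(n - min_len)) {
    for (b in (a + min_len):n) {
      sc <- oracle_score(substring(seq, a + 1, b))
      if (sc$gc > min_gc && sc$oe > min_oe) {
        cand[[length(cand) + 1L]] <- c(a, b)
      }
    }
  }
  if (!length(cand)) return(matrix(numeric(0), ncol = 2))
  m <- do.call(rbind, cand)
  picked <- NULL
  repeat {
    if (!nrow(m)) break
    len <- m[, 2] - m[, 1]
    best <- which(len == max(len))
    best <- best[which.min(m[best, 1])]
    sel <- m[best, ]
    picked <- rbind(picked, sel)
    keep <- m[, 2] <= sel[1] | m[, 1] >= sel[2]
    m <- m[keep, , drop = FALSE]
  }
  picked[order(picked[, 1]), , drop = FALSE]
}

# random DNA string
rand_seq <- function(n, probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

small_sim <- function(seed = 5, ...) {
  sim_config(seed = seed, n_chrom = 1, chrom_length = 3e5, n_genes = 10,
             n_cgis = 16, n_qtls = 2, dm_region_count = 4, ...)
}

# pooled count matrix of one stage from a site_matrix
sm_matrix_for <- function(sm, what, stage) {
  st <- sample_table(sm)
  as.matrix(sm[, paste0(what, "_", st$sample[st$stage == stage])])
}
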