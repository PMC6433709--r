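make_cgmap_sample <- function(pos, meth, total, context_class = "CG",
                              base = "C", chrom = "chr1") {
  tibble::tibble(chrom = chrom, base = base, pos = pos,
                 context_class = context_class, dinucleotide = "CG",
                 level = ifelse(total > 0, meth / total, 0),
                 meth = meth, total = total)
}

test_that("filtering keeps sites covered >= min_cov in every sample", {
  pos <- c(10, 20, 30, 40)
  samples <- list(
    Pre_1 = make_cgmap_sample(pos, c(1, 1, 1, 1), c(5, 5, 5, 9)),
    Pre_2 = make_cgmap_sample(pos, c(2, 2, 2, 2), c(5, 4, 5, 9)),
    In_1  = make_cgmap_sample(pos[-3], c(3, 3, 3), c(5, 5, 9)))
  st <- tibble::tibble(sample = c("Pre_1", "Pre_2", "In_1"),
                       stage = c("Pre", "Pre", "In"), replicate = c(1, 2, 1))
  sm <- load_and_filter(samples, st)
  # site 20 fails coverage in Pre_2 (4 < 5); site 30 is absent from In_1
  expect_equal(sm$pos, c(10, 40))

  # brute-force intersection-with-threshold oracle on a random fixture
  set.seed(19)
  rpos <- sort(sample(1:1000, 60))
  rs <- lapply(1:3, function(i) {
    keep <- sort(sample(seq_along(rpos), 50))
    tot <- sample(0:12, length(keep), replace = TRUE)
    make_cgmap_sample(rpos[keep], pmin(tot, sample(0:12, length(keep), TRUE)), tot)
  })
  names(rs) <- st$sample
  got <- load_and_filter(rs, st, min_cov = 5)
  want <- Reduce(intersect, lapply(rs, function(s) s$pos[s$total >= 5]))
  expect_equal(got$pos, sort(want))
  # monotonicity: raising min_cov never adds sites
  stricter <- load_and_filter(rs, st, min_cov = 8)
  expect_true(all(stricter$pos %in% got$pos))
})

test_that("malformed count files are rejected with context", {
  bad <- make_cgmap_sample(c(10, 20), c(6, 1), c(5, 5))  # meth > total
  st <- tibble::tibble(sample = c("a_1", "b_1"), stage = c("Pre", "In"),
                       replicate = c(1, 1))
  expect_error(load_and_filter(list(a_1 = bad, b_1 = bad), st), "malformed")
  dup <- make_cgmap_sample(c(10, 10), c(1, 1), c(5, 5))
  expect_error(load_and_filter(list(a_1 = dup, b_1 = dup), st), "duplicate")
  one <- list(a_1 = make_cgmap_sample(10, 1, 5))
  expect_error(load_and_filter(one, st[1, ]), "two samples")
})

test_that("site and group levels follow their definitions", {
  expect_equal(site_level(3, 5), 0.6)
  expect_equal(site_level(c(0, 7), c(7, 7)), c(0, 1))
  expect_error(site_level(1, 0), "total")
  expect_error(site_level(6, 5), "meth")
  # round trip: level * total recovers the methylated count
  set.seed(20)
  tot <- sample(1:30, 50, replace = TRUE)
  met <- rbinom(50, tot, 0.4)
  expect_equal(site_level(met, tot) * tot, as.numeric(met))

  # group level is the unweighted mean of replicate levels, which differs
  # from the pooled-read ratio under unequal coverage
  sm <- make_site_matrix(
    meth = matrix(c(1, 9, 5, 2, 4, 6, 0, 0, 0), 1),
    total = matrix(c(100, 10, 10, 10, 10, 10, 5, 5, 5), 1))
  gl <- group_levels(sm)
  expect_equal(gl$Pre, mean(c(1 / 100, 9 / 10, 5 / 10)))  # 0.47, not 15/120
  expect_equal(gl$In, 0.4)
  expect_equal(gl$Post, 0)
})

test_that("region levels average site group-levels within the region", {
  sm <- make_site_matrix(
    meth = matrix(rep(c(1, 3), each = 9), 2, byrow = TRUE),
    total = matrix(10, 2, 9), pos = c(100, 200))
  reg <- tibble::tibble(chrom = "chr1", start = c(0, 150, 500), end = c(300, 180, 600))
  out <- region_level(reg, sm, context = "CpG")
  expect_equal(out$n_sites, c(2, 0, 0))
  expect_equal(out$Pre[1], 0.2)  # mean of 0.1 and 0.3
  expect_true(is.na(out$Pre[2]))
})

test_that("binned profiles map sites to the documented bins", {
  # plus-strand gene, 4000 bp body -> 40 body bins of 100 bp
  genes <- tibble::tibble(
    gene_id = "g", chrom = "chr1", strand = "+", start = 10000, end = 14000,
    exons = list(tibble::tibble(start = 10000, end = 14000)))
  # sites: 100 bp before TSS (upstream bin 20), first body base (bin 21),
  # exactly on the first body-bin boundary (bin 21, boundary goes left),
  # one past it (bin 22), last body base (bin 60), 1 bp after TES (bin 61)
  pos <- c(9901, 10001, 10100, 10101, 14000, 14001)
  sm <- make_site_matrix(matrix(5, 6, 9), matrix(10, 6, 9), pos = pos)
  prof <- binned_profile(genes, sm, scheme = "gene", stages = "Pre")
  hit <- prof$bin[prof$n_sites > 0]
  expect_equal(hit, c(20, 21, 22, 60, 61))
  expect_equal(prof$n_sites[prof$bin == 21], 2)
  expect_equal(nrow(prof), 80)
  expect_equal(unique(prof$zone[prof$bin <= 20]), "upstream")

  # a minus-strand gene: a site 100 bp before its TSS (i.e. above end) also
  # lands in upstream bin 20
  gneg <- dplyr::mutate(genes, strand = "-")
  smn <- make_site_matrix(matrix(5, 1, 9), matrix(10, 1, 9), pos = 14100)
  pn <- binned_profile(gneg, smn, scheme = "gene", stages = "Pre")
  expect_equal(pn$bin[pn$n_sites > 0], 20)

  expect_warning(
    binned_profile(dplyr::mutate(genes, end = start + 30), sm, scheme = "gene"),
    "skipped")
})

test_that("binned profiles match a naive per-site oracle", {
  genes <- toy_genes(2, seed = 23)
  set.seed(24)
  n <- 120
  pos <- sort(sample(10000:70000, n))
  sm <- make_site_matrix(matrix(rbinom(n * 9, 10, 0.5), n, 9),
                         matrix(10, n, 9), pos = pos)
  prof <- binned_profile(genes, sm, scheme = "gene", stages = "Pre")
  gl <- group_levels(sm, "Pre")
  oracle_bin <- function(p, g) {
    p0 <- p - 1
    len <- g$end - g$start
    d <- if (g$strand == "+") {
      c(up = p0 - (g$start - 5000) + 1, body = p0 - g$start + 1, down = p0 - g$end + 1)
    } else {
      c(up = (g$end + 5000) - p0, body = g$end - p0, down = g$start - p0)
    }
    if (d["body"] >= 1 && d["body"] <= len) 20 + ceiling(d["body"] * 40 / len)
    else if (d["up"] >= 1 && d["up"] <= 5000) ceiling(d["up"] * 20 / 5000)
    else if (d["down"] >= 1 && d["down"] <= 5000) 60 + ceiling(d["down"] * 20 / 5000)
    else NA_real_
  }
  assigns <- list()
  for (g in seq_len(nrow(genes))) {
    for (i in seq_len(n)) {
      b <- oracle_bin(pos[i], genes[g, ])
      if (!is.na(b)) assigns[[length(assigns) + 1]] <- c(bin = b, level = gl$Pre[i])
    }
  }
  av <- as.data.frame(do.call(rbind, assigns))
  want <- tapply(av$level, av$bin, mean)
  got <- prof[prof$n_sites > 0, ]
  expect_equal(got$bin, as.integer(names(want)))
  expect_equal(got$mean_level, as.numeric(want))
  # conservation: total site-observations equal the oracle's assignments
  expect_equal(sum(got$n_sites), nrow(av))
})

test_that("window tracks count per tiled window with a fixed grid", {
  cl <- c(chr1 = 2.5e6)
  sites <- tibble::tibble(chrom = "chr1", pos = c(1, 5e5, 999999, 1000001))
  tr <- window_track(sites, cl, width = 1e6)
  expect_equal(tr$value, c(3, 1, 0))
  expect_equal(tr$win_start, c(0, 1e6, 2e6))
  expect_equal(tr$win_end, c(1e6, 2e6, 2.5e6))

  empty <- window_track(sites[0, ], cl, width = 1e6)
  expect_equal(empty$value, c(0, 0, 0))

  # intervals are assigned by midpoint
  iv <- tibble::tibble(chrom = "chr1", start = c(0, 999000), end = c(10, 1001002))
  expect_equal(window_track(iv, cl, width = 1e6)$value, c(1, 1, 0))

  # naive scan oracle with site values
  set.seed(25)
  s2 <- tibble::tibble(chrom = "chr1", pos = sample(1:2.5e6, 300),
                       level = runif(300))
  got <- window_track(s2, cl, width = 1e6, mode = "mean_level")
  want <- vapply(c(0, 1e6, 2e6), function(w) {
    v <- s2$level[s2$pos - 1 >= w & s2$pos - 1 < w + 1e6]
    mean(v)
  }, numeric(1))
  expect_equal(got$value, want)
})

test_that("pearson correlation matches the textbook formula", {
  x <- 1:10
  expect_equal(pearson_cor(x, x)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  set.seed(26)
  y <- x + rnorm(10)
  got <- pearson_cor(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(8 / (1 - r_hand^2))
  expect_equal(got$r, r_hand)
  expect_equal(got$p, 2 * pt(-abs(t_hand), 8))
  expect_warning(out <- pearson_cor(rep(1, 5), 1:5), "variance")
  expect_true(is.na(out$r))
})
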