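# independent two-tail Fisher oracle: hypergeometric pmf from choose(),
# summing the probabilities of all tables at most as likely as the observed
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (m1 == 0 || m2 == 0 || k == 0 || k == m1 + m2) return(1)
  supp <- max(0, k - m2):min(k, m1)
  pmf <- choose(m1, supp) * choose(m2, k - supp) / choose(m1 + m2, k)
  sum(pmf[pmf <= pmf[supp == a] * (1 + 1e-7)])
}

test_that("the two-tail Fisher p matches enumeration on forced cases", {
  expect_equal(fisher_exact_two_tail(20, 0, 0, 20), 2 / choose(40, 20))
  expect_equal(fisher_exact_two_tail(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_two_tail(0, 0, 3, 4), 1)  # empty margin convention
  set.seed(30)
  for (i in 1:100) {
    t <- rpois(4, 8)
    expect_equal(fisher_exact_two_tail(t[1], t[2], t[3], t[4]),
                 oracle_fisher(t[1], t[2], t[3], t[4]), tolerance = 1e-12)
    expect_equal(fisher_exact_two_tail(t[1], t[2], t[3], t[4]),
                 stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment equals the step-up formula and a naive oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  naive_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    # step-up: q at rank i is min over ranks j >= i of m * p_(j) / j
    for (i in seq_len(m)) q[o[i]] <- min(1, min(m * p[o][i:m] / (i:m)))
    q
  }
  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), naive_bh(p))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("site-level DM calls pool reads and apply both thresholds", {
  # three sites: a clean full-swing difference, a 10% difference with huge
  # counts (significant but below the delta rule), and a difference of
  # exactly 0.20 (strict threshold excludes it)
  meth <- rbind(c(20, 20, 20, 0, 0, 0, 0, 0, 0),
                c(550, 550, 550, 450, 450, 450, 1, 1, 1),
                c(500, 500, 500, 300, 300, 300, 1, 1, 1))
  total <- rbind(c(20, 20, 20, 20, 20, 20, 20, 20, 20),
                 matrix(1000, 2, 9))
  sm <- make_site_matrix(meth, total)
  res <- dm_site_test(sm, "PreVsIn")
  expect_equal(res$delta, c(1, 0.10, 0.20))
  expect_true(res$is_dm[1])
  expect_equal(res$polarity[1], "hyper_in_a")
  expect_false(res$is_dm[2])   # delta rule: more than 20% required
  expect_false(res$is_dm[3])   # exactly 20% is not "more than 20%"
  expect_lt(res$q[2], 0.05)    # it fails on delta, not on significance

  # symmetry: swapping the groups negates delta, flips polarity, keeps p
  rev <- dm_site_test(sm, c("In", "Pre"))
  expect_equal(rev$delta, -res$delta)
  expect_equal(rev$p, res$p)
  expect_equal(rev$polarity[1], "hyper_in_b")
})

test_that("q-values are adjusted within context strata", {
  set.seed(32)
  n <- 40
  meth <- cbind(matrix(rbinom(n * 3, 20, 0.5), n), matrix(rbinom(n * 3, 20, 0.5), n),
                matrix(rbinom(n * 3, 20, 0.5), n))
  sm <- make_site_matrix(meth, matrix(20, n, 9),
                         context = rep(c("CpG", "CpH"), each = n / 2))
  res <- dm_site_test(sm, "PreVsIn")
  for (ctx in c("CpG", "CpH")) {
    sub <- res[res$context == ctx, ]
    expect_equal(sub$q, bh_fdr(sub$p))
  }
})

test_that("the region test follows Student's t with its edge conventions", {
  # identical replicate means -> t = 0, p = 1
  expect_equal(methylrrbs:::student_t_p(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3)), 1)
  # strong separation: cross-check against stats::t.test (pooled variance)
  a <- c(0.8, 0.82, 0.81); b <- c(0.2, 0.22, 0.21)
  expect_lt(methylrrbs:::student_t_p(a, b), 0.001)
  expect_equal(methylrrbs:::student_t_p(a, b),
               stats::t.test(a, b, var.equal = TRUE)$p.value)
  expect_equal(methylrrbs:::student_t_p(a, b, var_equal = FALSE),
               stats::t.test(a, b)$p.value)
  # zero pooled variance conventions
  expect_equal(methylrrbs:::student_t_p(c(.5, .5, .5), c(.5, .5, .5)), 1)
  expect_equal(methylrrbs:::student_t_p(c(.6, .6, .6), c(.2, .2, .2)), 0)
})

test_that("regions need 20 covered sites to be tested", {
  set.seed(33)
  n <- 39  # 19 sites in region 1, 20 in region 2
  pos <- c(seq(101, by = 2, length.out = 19), seq(1001, by = 2, length.out = 20))
  meth <- cbind(matrix(2, n, 3), matrix(8, n, 3), matrix(5, n, 3))
  sm <- make_site_matrix(meth + rbinom(n * 9, 2, 0.5), matrix(12, n, 9), pos = pos)
  regions <- tibble::tibble(region_id = c("r1", "r2"), chrom = "chr1",
                            start = c(100, 1000), end = c(200, 1100))
  res <- dm_region_test(regions, sm, "PreVsIn")
  expect_equal(res$n_sites, c(19, 20))
  expect_equal(res$tested, c(FALSE, TRUE))
  expect_true(is.na(res$p[1]))
  expect_true(res$is_dm[2])  # 2/12 vs 8/12 across all sites
})

test_that("DM-regarding gene sets use extended spans", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
    start = c(10000, 50000), end = c(20000, 60000),
    exons = list(tibble::tibble(start = 10000, end = 20000),
                 tibble::tibble(start = 50000, end = 60000)))
  dm <- tibble::tibble(chrom = "chr1", pos = c(24000, 40000),
                       is_dm = c(TRUE, TRUE))
  # 24000 is inside g1's downstream flank; 40000 is in no extended span
  expect_equal(dm_regarding_genes(dm, genes), "g1")
  expect_equal(dm_regarding_genes(dm[dm$pos == 40000, ], genes), character(0))

  # DMIs: overlap by >= 1 bp with the extended span counts
  dmis <- tibble::tibble(chrom = "chr1", start = c(4800, 30000),
                         end = c(5200, 31000), is_dm = c(TRUE, TRUE))
  expect_equal(dmi_regarding_genes(dmis, genes), "g1")  # straddles g1's flank edge
  only_far <- dmis[2, ]
  expect_equal(dmi_regarding_genes(only_far, genes), character(0))

  # brute-force cross-check on random DM sites
  set.seed(34)
  rnd <- tibble::tibble(chrom = "chr1", pos = sample(1:70000, 200), is_dm = TRUE)
  want <- sort(unique(unlist(lapply(seq_len(2), function(i) {
    if (any(rnd$pos - 1 >= genes$start[i] - 5000 & rnd$pos - 1 < genes$end[i] + 5000))
      genes$gene_id[i] else NULL
  }))))
  expect_equal(dm_regarding_genes(rnd, genes), want)
})

test_that("no DM calls arise on null data beyond the FDR level", {
  cfg <- sim_config(seed = 12, n_chrom = 1, chrom_length = 3e5, n_genes = 8,
                    n_cgis = 12, n_qtls = 0, dm_site_fraction = 0,
                    dm_region_count = 0,
                    stage_deltas = c(Pre = 0, In = 0, Post = 0))
  sim <- simulate_methylome(cfg)
  sm <- load_and_filter(sim$samples, sim$sample_table)
  expect_gte(nrow(sm), 2000)
  res <- dm_site_test(sm, "PreVsIn")
  mc_se <- sqrt(0.05 * 0.95 / nrow(res))
  expect_lte(mean(res$is_dm), 0.05 + 3 * mc_se)
})
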