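test_that("MspI digestion keeps exactly the size-selected inter-cut fragments", {
  # cuts between C and CGG; fragments are inter-cut intervals
  seq <- paste0(strrep("A", 50), "CCGG", strrep("T", 146), "CCGG",
                strrep("A", 100), "CCGG")
  fr <- msp1_digest(seq)
  # cuts fall after the first C of each CCGG: 0-based boundaries 51, 201,
  # 305 -> fragments of 150 bp (retained) and 104 bp (below 110, dropped)
  expect_equal(fr$start, 51)
  expect_equal(fr$end, 201)

  # boundary rule: 100 bp and 221 bp excluded, 110 and 220 retained
  mk <- function(gaps) paste0("CCGG", paste0(strrep("A", gaps - 4), "CCGG", collapse = ""))
  lens <- function(gaps) { f <- msp1_digest(mk(gaps)); f$end - f$start }
  expect_equal(lens(100), numeric(0))
  expect_equal(lens(221), numeric(0))
  expect_equal(lens(110), 110)
  expect_equal(lens(220), 220)

  expect_equal(nrow(msp1_digest(strrep("AT", 500))), 0)
})

test_that("digestion equals a brute-force scan on a random sequence", {
  set.seed(21)
  seq <- rand_seq(2000, c(A = .2, C = .3, G = .3, T = .2))
  got <- msp1_digest(seq)
  # oracle: locate every CCGG by direct position test, enumerate inter-cut
  # intervals, filter by size
  ch <- strsplit(seq, "")[[1]]
  cuts <- which(ch == "C" & c(ch[-1], "") == "C" &
                  c(ch[-(1:2)], "", "") == "G" & c(ch[-(1:3)], "", "", "") == "G")
  s <- cuts[-length(cuts)]; e <- cuts[-1]
  keep <- (e - s) >= 110 & (e - s) <= 220
  expect_equal(got$start, as.numeric(s[keep]))
  expect_equal(got$end, as.numeric(e[keep]))
})

test_that("the generator is deterministic and honours the feature counts", {
  cfg <- small_sim(seed = 99)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$cgis, g2$cgis)

  cfg5 <- sim_config(seed = 4, n_chrom = 1, chrom_length = 1e5, n_genes = 3,
                     n_cgis = 5, n_qtls = 1)
  g5 <- generate_genome(cfg5)
  expect_equal(nrow(g5$cgis), 5)
  isl_seq <- substring(g5$genome[[1]], g5$cgis$start + 1, g5$cgis$end)
  expect_true(all(score_segment(isl_seq)$gc_fraction > 0.5))

  sim1 <- simulate_methylome(cfg)
  sim2 <- simulate_methylome(cfg)
  expect_identical(sim1$samples, sim2$samples)
  expect_identical(sim1$truth, sim2$truth)
})

test_that("the generator rejects configurations that do not fit", {
  expect_error(generate_genome(sim_config(n_chrom = 1, chrom_length = 5e4,
                                          n_genes = 10, n_cgis = 2)), "fit")
  expect_error(sim_config(frag_min = 300, frag_max = 200), "frag_min")
  expect_error(sim_config(stage_deltas = c(Pre = 0, In = -0.01, Post = 0)),
               "non-increasing")
  expect_error(sim_config(cph_level = 1.5), "fractions")
})

test_that("the island caller recovers planted islands from a generated genome", {
  cfg <- sim_config(seed = 3, n_chrom = 1, chrom_length = 4e5, n_genes = 12,
                    n_cgis = 15)
  gen <- generate_genome(cfg)
  called <- call_cgis(gen$genome[[1]])
  recovered <- vapply(seq_len(nrow(gen$cgis)), function(i) {
    ov <- pmin(called$end, gen$cgis$end[i]) - pmax(called$start, gen$cgis$start[i])
    ro <- pmin(ov / (called$end - called$start),
               ov / (gen$cgis$end[i] - gen$cgis$start[i]))
    any(ro >= 0.8)
  }, logical(1))
  expect_gte(mean(recovered), 0.8)
})

test_that("every emitted site lies inside a retained fragment, on both strands", {
  cfg <- small_sim(seed = 5)
  sim <- simulate_methylome(cfg)
  smp <- sim$samples[[1]]
  inside <- methylrrbs:::sites_in_intervals(smp$chrom, smp$pos, sim$fragments)
  expect_true(all(inside))
  expect_setequal(unique(smp$base), c("C", "G"))
})

test_that("context labels match a direct reference scan of the fragments", {
  cfg <- small_sim(seed = 5)
  sim <- simulate_methylome(cfg)
  ch <- strsplit(sim$genome[[1]], "")[[1]]
  smp <- sim$samples[[1]]
  # plus-strand cytosine: CpG iff the next reference base is G;
  # minus-strand (reported at the Watson G): CpG iff the previous base is C
  want_cpg <- ifelse(smp$base == "C", c(ch, "")[smp$pos + 1] == "G",
                     c("", ch)[smp$pos] == "C")
  expect_equal(smp$context_class == "CG", want_cpg)
  # direct count cross-check over all cytosines in fragments
  in_frag <- rep(FALSE, length(ch))
  for (i in seq_len(nrow(sim$fragments))) {
    in_frag[(sim$fragments$start[i] + 1):sim$fragments$end[i]] <- TRUE
  }
  n_cpg_plus <- sum(ch == "C" & c(ch[-1], "") == "G" & in_frag)
  n_cpg_minus <- sum(ch == "G" & c("", ch[-length(ch)]) == "C" & in_frag)
  sites <- methylrrbs:::enumerate_sites(ch, sim$fragments, "chr1")
  expect_equal(sum(sites$context == "CpG"), n_cpg_plus + n_cpg_minus)
})

test_that("simulated levels track the configured means and planted effects", {
  # open-sea mean: no islands, no deltas, no planted effects
  cfg <- sim_config(seed = 8, n_chrom = 1, chrom_length = 3.5e6, n_genes = 0,
                    n_cgis = 0, n_qtls = 0, dm_site_fraction = 0,
                    dm_region_count = 0,
                    stage_deltas = c(Pre = 0, In = 0, Post = 0))
  gen <- generate_genome(cfg)
  fr <- dplyr::mutate(msp1_digest(gen$genome[[1]]), chrom = "chr1", .before = 1)
  counts <- simulate_counts(gen$genome, fr, cfg, "Pre", 1)
  cpg <- counts[counts$context_class == "CG" & counts$total > 0, ]
  expect_gte(nrow(cpg), 1e4)
  lvl <- sum(cpg$meth) / sum(cpg$total)
  expect_lt(abs(lvl - cfg$cpg_level_open), 0.02)
  cph <- counts[counts$context_class != "CG", ]
  expect_lt(abs(sum(cph$meth) / sum(cph$total) - cfg$cph_level), 0.005)

  # planted site effects are visible in pooled levels at decent coverage
  sim <- simulate_methylome(small_sim(seed = 5))
  sm <- load_and_filter(sim$samples, sim$sample_table)
  tr <- sim$truth$dm_site_comparisons
  tr <- tr[tr$comparison == "PreVsIn" & abs(tr$expected_delta) == 0.5, ]
  key <- paste(sm$chrom, sm$pos)
  i <- match(paste(tr$chrom, tr$pos), key)
  tr <- tr[!is.na(i), ]; i <- i[!is.na(i)]
  ma <- rowSums(as.matrix(sm[i, c("meth_Pre_1", "meth_Pre_2", "meth_Pre_3")]))
  ta <- rowSums(as.matrix(sm[i, c("total_Pre_1", "total_Pre_2", "total_Pre_3")]))
  mb <- rowSums(as.matrix(sm[i, c("meth_In_1", "meth_In_2", "meth_In_3")]))
  tb <- rowSums(as.matrix(sm[i, c("total_In_1", "total_In_2", "total_In_3")]))
  ok <- ta >= 20 & tb >= 20
  delta <- (ma / ta - mb / tb) * sign(tr$expected_delta)
  expect_gte(mean(delta[ok] >= 0.3), 0.9)
})

test_that("decreasing stage deltas order the genome-average CpG level", {
  cfg <- sim_config(seed = 2, n_chrom = 1, chrom_length = 1.5e6, n_genes = 40,
                    n_cgis = 60, n_qtls = 2, dm_site_fraction = 0,
                    dm_region_count = 0)
  sim <- simulate_methylome(cfg)
  sm <- load_and_filter(sim$samples, sim$sample_table)
  gl <- group_levels(sm)
  cpg <- gl[gl$context == "CpG", ]
  expect_gt(mean(cpg$Pre), mean(cpg$In))
  expect_gt(mean(cpg$In), mean(cpg$Post))
})

test_that("written outputs round-trip through the package readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 6, n_chrom = 1, chrom_length = 1e5, n_genes = 3,
                    n_cgis = 5, n_qtls = 1, dm_region_count = 2)
  sim <- simulate_methylome(cfg, outdir = dir)
  genome <- read_fasta(file.path(dir, "genome.fa"))
  expect_identical(unname(genome), unname(sim$genome))
  genes <- read_gene_table(file.path(dir, "genes.bed"))
  expect_equal(genes$start, sim$genes$start)
  expect_equal(genes$exons, sim$genes$exons)
  qtls <- read_bed(file.path(dir, "qtls.bed"))
  expect_equal(qtls$start, sim$qtls$start)
  smp <- read_cgmap(file.path(dir, "Pre_1.cgmap.tsv"))
  expect_equal(nrow(smp), nrow(sim$samples$Pre_1))
  expect_equal(smp$meth, sim$samples$Pre_1$meth)
  expect_equal(smp$context == "CpG", sim$samples$Pre_1$context_class == "CG")
})
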