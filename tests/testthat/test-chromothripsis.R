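test_that("SV clustering matches brute-force transitive closure", {
  # 8 SVs inside 2 Mb form one cluster
  near <- sv_df("chr1", seq(1e6, 2.4e6, by = 2e5), "+",
                "chr1", seq(1.1e6, 2.5e6, by = 2e5), "-", "DEL")
  cl <- cluster_intrachromosomal_svs(near)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_sv, 8L)
  # two groups 10 Mb apart stay separate
  far <- rbind(near,
               sv_df("chr1", seq(14e6, 14.4e6, by = 2e5), "+",
                     "chr1", seq(14.1e6, 14.5e6, by = 2e5), "-", "DEL"))
  expect_equal(nrow(cluster_intrachromosomal_svs(far)), 2L)
  # randomized agreement with the transitive-closure oracle
  set.seed(77)
  for (rep in 1:25) {
    m <- sample(2:9, 1)
    p1 <- round(runif(m, 0, 3e7)); p2 <- p1 + round(runif(m, 1e4, 4e6))
    svs <- sv_df("chr5", p1, "+", "chr5", p2, "-", "DEL")
    got <- cluster_intrachromosomal_svs(svs, max_gap = 1e6)
    labels_got <- integer(m)
    for (k in seq_len(nrow(got))) labels_got[got$sv_idx[[k]]] <- k
    labels_oracle <- oracle_sv_clusters(p1, p2, 1e6)
    # same partition up to relabelling
    expect_equal(length(unique(labels_got)), length(unique(labels_oracle)))
    expect_true(all(tapply(labels_oracle, labels_got,
                           function(v) length(unique(v))) == 1))
  }
})

test_that("oscillation counting finds the longest two-state run", {
  expect_equal(count_oscillations(data.frame(tcn = c(2, 3, 2, 3, 2, 3, 2, 3,
                                                     2))), 8L)
  expect_equal(count_oscillations(data.frame(tcn = rep(2, 9))), 0L)
  expect_equal(count_oscillations(data.frame(tcn = c(2, 3, 4, 3))), 2L)
  set.seed(31)
  for (rep in 1:50) {
    cn <- sample(1:4, sample(2:12, 1), replace = TRUE)
    expect_equal(count_oscillations(data.frame(tcn = cn)),
                 oracle_oscillations(cn),
                 info = paste(cn, collapse = ","))
  }
})

test_that("breakpoint enrichment is a binomial tail", {
  p <- breakpoint_enrichment_pvalue(20, 1e6, 20, 1e8)
  expect_equal(p, 0.01^20, tolerance = 1e-6)
  expect_lt(p, 0.05)
  expect_equal(breakpoint_enrichment_pvalue(5, 1e8, 5, 1e8), 1)
  expect_error(breakpoint_enrichment_pvalue(10, 1e6, 5, 1e8), "exceeds")
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(1:30, 1); x <- sample(0:n, 1); frac <- runif(1, 0.001, 0.9)
    if (x == 0) next
    expect_equal(breakpoint_enrichment_pvalue(x, frac * 1e8, n, 1e8),
                 oracle_binom_tail(x, n, frac), tolerance = 1e-10)
  }
  # monotone decreasing in the observed count
  ps <- vapply(1:20, breakpoint_enrichment_pvalue, numeric(1),
               region_len = 1e6, n_genome = 20, genome_len = 1e8)
  expect_true(all(diff(ps) < 0))
})

test_that("join randomness is a symmetric chi-square GOF", {
  expect_equal(join_randomness_pvalue(c(2, 2, 2, 2)), 1)
  expect_equal(join_randomness_pvalue(c(8, 0, 0, 0)),
               pchisq(24, 3, lower.tail = FALSE))
  expect_lt(join_randomness_pvalue(c(8, 0, 0, 0)), 1e-4)
  expect_equal(join_randomness_pvalue(c(5, 1, 0, 2)),
               join_randomness_pvalue(c(0, 2, 5, 1)))
  expect_error(join_randomness_pvalue(c(0, 0, 0, 0)), "at least one")
})

test_that("the criteria engine calls injected events and rejects small ones", {
  cfg <- simulation_config(n_samples = 1, logr_noise_sd = 0, rng_seed = 314)
  p <- simulate_segment_profile(cfg, 1, is_wgd = FALSE, purity = 0.5)
  set.seed(11)
  p10 <- inject_chromothripsis(p, "chr4", 10)
  m <- ploidy_model(p10$purity, p10$ploidy)
  seg <- p10$segments
  seg$tcn <- as.numeric(rescale_total_copy_number(seg$logR, m, warn = FALSE))
  ct <- call_chromothripsis(p10$sv, seg, cfg$genome)
  expect_true(any(ct$high_confidence))
  # 3 SVs: below the >6 cluster criterion
  set.seed(11)
  p3 <- inject_chromothripsis(p, "chr4", 3)
  m3 <- ploidy_model(p3$purity, p3$ploidy)
  seg3 <- p3$segments
  seg3$tcn <- as.numeric(rescale_total_copy_number(seg3$logR, m3,
                                                   warn = FALSE))
  ct3 <- call_chromothripsis(p3$sv, seg3, cfg$genome)
  expect_false(any(ct3$high_confidence))
  # 5 SVs, oscillations forced high by hand: still fails criterion (i)
  set.seed(11)
  p5 <- inject_chromothripsis(p, "chr4", 5)
  seg5 <- p5$segments
  seg5$tcn <- as.numeric(rescale_total_copy_number(
    seg5$logR, ploidy_model(p5$purity, p5$ploidy), warn = FALSE))
  ct5 <- call_chromothripsis(p5$sv, seg5, cfg$genome)
  expect_false(any(ct5$high_confidence))
})

test_that("ecDNA/chromothripsis overlap is measured in intersected bases", {
  calls <- data.frame(chrom = "chr1", start = 5e6, end = 6e6,
                      high_confidence = TRUE)
  disjoint <- data.frame(chrom = "chr1", start = 1e6, end = 2e6)
  expect_equal(overlap_ecdna_chromothripsis(disjoint, calls),
               list(any_overlap = FALSE, overlap_bp = 0))
  same <- data.frame(chrom = "chr1", start = 5e6, end = 6e6)
  expect_equal(overlap_ecdna_chromothripsis(same, calls)$overlap_bp, 1e6)
  nested <- data.frame(chrom = "chr1", start = 5.5e6, end = 5.51e6)
  ov <- overlap_ecdna_chromothripsis(nested, calls)
  expect_true(ov$any_overlap)
  expect_equal(ov$overlap_bp, 1e4)
  # low-confidence regions never count
  calls$high_confidence <- FALSE
  expect_false(overlap_ecdna_chromothripsis(same, calls)$any_overlap)
})
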