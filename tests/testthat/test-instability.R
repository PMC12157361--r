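test_that("WGD calling uses a strict length-weighted majority", {
  all1 <- seg_df("chr1", c(0, 5e6), c(5e6, 10e6), major = c(1, 1))
  expect_false(call_wgd(all1))
  # 60% of genome length at major 3
  mix <- seg_df("chr1", c(0, 6e6), c(6e6, 10e6), major = c(3, 1))
  expect_true(call_wgd(mix))
  # exactly 50% does not qualify ("more than 50%" is strict)
  half <- seg_df("chr1", c(0, 5e6), c(5e6, 10e6), major = c(3, 1))
  expect_false(call_wgd(half))
  expect_error(call_wgd(half[0, ]), "empty")
})

test_that("WGD calling is invariant to segment subdivision", {
  base <- seg_df("chr1", c(0, 6e6, 8e6), c(6e6, 8e6, 10e6),
                 major = c(3, 1, 1))
  expect_true(call_wgd(base))
  # split the doubled segment into three pieces: length reading unchanged
  split <- rbind(seg_df("chr1", c(0, 2e6, 4e6), c(2e6, 4e6, 6e6),
                        major = rep(3, 3)), base[-1, ])
  expect_identical(call_wgd(split), call_wgd(base))
  # a count-based reading flips on this example; the flag exposes it
  expect_false(call_wgd(base, weight = "count"))
  expect_true(call_wgd(split, weight = "count"))
})

test_that("wGII matches analytic values and stays within [0, 1]", {
  diploid <- do.call(rbind, lapply(paste0("chr", 1:22), function(ch)
    seg_df(ch, 0, 10e6, tcn = 2)))
  expect_equal(compute_wgii(diploid)$wgii, 0)
  # one autosome fully aberrant out of 22
  one <- diploid
  one$tcn[one$chrom == "chr7"] <- 4
  expect_equal(compute_wgii(one)$wgii, 1 / 22, tolerance = 1e-12)
  # equal-length 1/3 oscillation: ploidy 2, every base aberrant, wGII = 1
  burst <- do.call(rbind, lapply(paste0("chr", 1:22), function(ch)
    seg_df(ch, c(0, 5e6), c(5e6, 10e6), tcn = c(1, 3))))
  expect_equal(compute_wgii(burst)$wgii, 1)
  set.seed(9)
  rnd <- do.call(rbind, lapply(paste0("chr", 1:22), function(ch)
    seg_df(ch, c(0, 4e6), c(4e6, 10e6), tcn = sample(0:8, 2))))
  wr <- compute_wgii(rnd)$wgii
  expect_gte(wr, 0)
  expect_lte(wr, 1)
  # subdivision invariance
  sub <- rbind(seg_df("chr1", c(0, 2e6), c(2e6, 4e6),
                      tcn = rep(rnd$tcn[1], 2)), rnd[-1, ])
  expect_equal(compute_wgii(sub)$wgii, wr, tolerance = 1e-12)
})

test_that("telomeric read counting applies the 7-repeat threshold", {
  r7 <- strrep("TTAGGG", 7)
  r6 <- strrep("TTAGGG", 6)
  expect_equal(count_telomeric_reads(r7), 1L)
  expect_equal(count_telomeric_reads(r6), 0L)
  set.seed(3)
  pad <- function(s) paste0(
    paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""), s,
    paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""))
  emb <- pad(strrep("CCCTAA", 7))
  expect_equal(count_telomeric_reads(emb), 1L)
  # regex-count cross-check on the embedded read
  expect_gte(lengths(regmatches(emb, gregexpr("CCCTAA", emb)))[1], 7)
  expect_equal(count_telomeric_reads(c(r7, r6, emb)), 2L)
  expect_equal(count_telomeric_reads(tolower(r7)), 1L)
})

test_that("sample telomere length is the read-weighted group mean", {
  one <- data.frame(n_reads = 100, tl_kb = 6.2)
  expect_equal(estimate_sample_tl(one), 6.2)
  eq <- data.frame(n_reads = c(100, 100), tl_kb = c(5, 10))
  expect_equal(estimate_sample_tl(eq), 7.5)
  w13 <- data.frame(n_reads = c(100, 300), tl_kb = c(4, 8))
  expect_equal(estimate_sample_tl(w13), 7)
  # weighted mean lies between group extremes
  set.seed(8)
  g <- data.frame(n_reads = sample(1e3:1e5, 5),
                  n_telomeric = sample(50:500, 5))
  tl <- estimate_sample_tl(g, scale = 100)
  per <- 100 * g$n_telomeric / g$n_reads
  expect_gte(tl, min(per))
  expect_lte(tl, max(per))
  expect_error(estimate_sample_tl(data.frame(n_reads = 0, n_telomeric = 0)),
               "zero")
})

test_that("tumor/normal telomere ratio is scale-free", {
  expect_equal(tl_log2_ratio(5, 5), 0)
  expect_equal(tl_log2_ratio(8, 4), 1)
  g <- data.frame(n_reads = c(1e4, 2e4), n_telomeric = c(120, 300))
  r1 <- tl_log2_ratio(estimate_sample_tl(g, scale = 1),
                      estimate_sample_tl(g[2:1, ], scale = 1))
  r2 <- tl_log2_ratio(estimate_sample_tl(g, scale = 2),
                      estimate_sample_tl(g[2:1, ], scale = 2))
  expect_equal(r1, r2)
  expect_error(tl_log2_ratio(0, 5), "positive")
})

test_that("mitochondrial copy number corrects for the normal admixture", {
  # pure tumor: mt_cn = depth ratio times ploidy
  m1 <- ploidy_model(1, 3)
  expect_equal(mito_copy_number(100, 10, 50, 10, m1), 10 * 3)
  # half-and-half mixture with equal tumor/normal depth ratios: 2 * R_n
  m2 <- ploidy_model(0.5, 2)
  expect_equal(mito_copy_number(80, 10, 80, 10, m2), 2 * 8)
  # forward-model inversion: known tumor-cell mt_cn recovered exactly
  rho <- 0.35; psi <- 3.2; mt <- 500; mn <- 180
  pe <- rho * psi + 2 * (1 - rho)
  r_t <- (rho * mt + (1 - rho) * mn) / pe
  got <- mito_copy_number(r_t * 30, 30, mn / 2 * 28, 28,
                          ploidy_model(rho, psi))
  expect_equal(got, mt, tolerance = 1e-9)
  expect_error(mito_copy_number(0, 1, 1, 1, m1), "positive")
})
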