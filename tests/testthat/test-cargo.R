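genes_fixture <- function() {
  data.frame(
    name = c("MDM2", "B2M", "HOUSE1"),
    chrom = "chr12", start = c(2e6, 4e6, 6e6), end = c(2.1e6, 4.05e6, 6.2e6),
    strand = c("+", "-", "+"),
    is_oncogene = c(TRUE, FALSE, FALSE),
    is_immunomodulatory = c(FALSE, TRUE, FALSE),
    is_tumor_suppressor = FALSE, stringsAsFactors = FALSE)
}

test_that("promoters are 1 kb upstream of the TSS, strand-aware, clipped", {
  g <- data.frame(name = "G", chrom = "chr1", start = 5000, end = 8000,
                  strand = "+", stringsAsFactors = FALSE)
  p <- promoter_regions(g)
  expect_equal(c(p$start, p$end), c(4000, 5000))
  g$strand <- "-"
  p <- promoter_regions(g)
  expect_equal(c(p$start, p$end), c(8000, 9000))
  near0 <- data.frame(name = "H", chrom = "chr1", start = 200, end = 900,
                      strand = "+", stringsAsFactors = FALSE)
  p0 <- promoter_regions(near0)
  expect_equal(c(p0$start, p0$end), c(0, 200))
})

test_that("cargo annotation enforces full containment for genes/enhancers", {
  ec <- data.frame(chrom = "chr12", start = 1.5e6, end = 5e6)
  genes <- genes_fixture()
  enh_half <- data.frame(chrom = "chr12", start = 4.9e6, end = 5.3e6)
  enh_in <- data.frame(chrom = "chr12", start = 3e6, end = 3.01e6)
  a <- annotate_ecdna(ec, genes, enhancers = enh_half)
  expect_true(a$has_oncogene)
  expect_false(a$has_enhancer)   # half-overlapping enhancer never counts
  a2 <- annotate_ecdna(ec, genes, enhancers = enh_in)
  expect_true(a2$has_enhancer)
  # promoters count on >= 1 bp overlap
  prom <- promoter_regions(genes)
  a3 <- annotate_ecdna(data.frame(chrom = "chr12", start = 1.99e6,
                                  end = 1.9995e6), genes[0, ],
                       promoters = prom)
  expect_true(a3$has_promoter)
  # nothing matched: unknown
  a4 <- annotate_ecdna(data.frame(chrom = "chr1", start = 0, end = 1e4),
                       genes)
  expect_true(a4$unknown)
})

test_that("containment is safe under interval subdivision", {
  genes <- genes_fixture()
  whole <- data.frame(chrom = "chr12", start = 1.5e6, end = 5e6)
  # split at a point inside MDM2: containment must not change
  split <- data.frame(chrom = "chr12", start = c(1.5e6, 2.05e6),
                      end = c(2.05e6, 5e6))
  expect_equal(annotate_ecdna(whole, genes)$genes,
               annotate_ecdna(split, genes)$genes)
})

test_that("cargo classes follow the oncogene-first priority", {
  both <- list(has_oncogene = TRUE, has_immunomodulatory = FALSE,
               has_other_gene = TRUE, has_enhancer = TRUE,
               has_promoter = TRUE, unknown = FALSE)
  expect_equal(classify_cargo(both), "oncogene")
  # immunomodulatory flag is suppressed whenever an oncogene rides along
  ec <- data.frame(chrom = "chr12", start = 1.5e6, end = 5e6)
  a <- annotate_ecdna(ec, genes_fixture())
  expect_true(a$has_oncogene)
  expect_false(a$has_immunomodulatory)
  immuno_only <- annotate_ecdna(data.frame(chrom = "chr12", start = 3.9e6,
                                           end = 4.2e6), genes_fixture())
  expect_equal(classify_cargo(immuno_only), "immunomodulatory")
  reg <- list(has_oncogene = FALSE, has_immunomodulatory = FALSE,
              has_other_gene = FALSE, has_enhancer = TRUE,
              has_promoter = FALSE, unknown = FALSE)
  expect_equal(classify_cargo(reg), "regulatory_only")
})

test_that("driver-mutation calls equal the six-clause disjunction", {
  expect_true(classify_driver_mutation("truncating",
                                       is_tumor_suppressor = TRUE))
  expect_false(classify_driver_mutation("truncating",
                                        is_tumor_suppressor = FALSE))
  expect_true(classify_driver_mutation("missense", recurrence_count = 3))
  expect_false(classify_driver_mutation("missense", recurrence_count = 2,
                                        boostdm_score = 0.4))
  expect_true(classify_driver_mutation("other", boostdm_score = 0.51))
  expect_true(classify_driver_mutation("other",
                                       oncokb_label = "Likely Oncogenic"))
  expect_false(classify_driver_mutation("other", oncokb_label = "VUS"))
  expect_true(classify_driver_mutation("other", mc3_flag = TRUE))
  expect_true(classify_driver_mutation("missense", is_tumor_suppressor = TRUE,
                                       pathogenicity_label = "likely pathogenic"))
  # randomized records against the literal disjunction
  set.seed(55)
  for (rep in 1:200) {
    cons <- sample(c("truncating", "missense", "other"), 1)
    tsg <- sample(c(TRUE, FALSE), 1)
    rec <- sample(1:5, 1)
    boost <- sample(c(NA, runif(1)), 1)
    okb <- sample(c(NA, "Oncogenic", "Likely Oncogenic", "Inconclusive"), 1)
    mc3 <- sample(c(TRUE, FALSE), 1)
    path <- sample(c(NA, "likely pathogenic", "benign"), 1)
    expect_identical(
      classify_driver_mutation(cons, tsg, rec, boost, okb, mc3, path),
      oracle_driver(cons, tsg, rec, boost, okb, mc3, path))
  }
})
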