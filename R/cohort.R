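# Cohort-level simulation: event flags first (so genomic injections agree
# with the clinical table), then genomes, then covariates and survival.

# intercept alpha such that the marginal ecDNA prevalence matches `target`
# when logit P(ecDNA) = alpha + log(or) * is_wgd and P(WGD) = w
solve_ecdna_intercept <- function(target, w, or) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  f <- function(a) {
    (1 - w) * stats::plogis(a) + w * stats::plogis(a + log(or)) - target
  }
  stats::uniroot(f, c(-30, 30), tol = 1e-12)$root
}

#' Simulate the clinical/covariate table of a cohort
#'
#' Draws demographic and clinical covariates (age, sex, genetic ancestry,
#' histology, stage, smoking status), assigns ecDNA status from a logistic
#' model whose linear predictor carries `log(effect_or_wgd_ecdna) * is_wgd`
#' (with the intercept solved so the marginal prevalence matches
#' `cfg$ecdna_fraction`), and draws overall survival as exponential with the
#' hazard multiplied by `effect_hr_ecdna` for ecDNA-positive samples, with
#' independent exponential censoring tuned to `cfg$censoring_rate`.
#'
#' @param truth Data frame with at least `sample_id` and logical `is_wgd`;
#'   one row per sample.
#' @param cfg A [simulation_config()].
#' @return Data frame: `sample_id`, `is_wgd`, `has_ecdna`, `age`, `sex`,
#'   `ancestry`, `histology`, `stage`, `smoking`, `purity`, `time`, `event`.
#' @export
simulate_clinical <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"), all(c("sample_id", "is_wgd") %in%
                                               names(truth)))
  n <- nrow(truth)
  alpha <- solve_ecdna_intercept(cfg$ecdna_fraction, cfg$wgd_fraction,
                                 cfg$effect_or_wgd_ecdna)
  p_ecdna <- stats::plogis(alpha + log(cfg$effect_or_wgd_ecdna) * truth$is_wgd)
  has_ecdna <- stats::runif(n) < p_ecdna
  age <- round(pmin(pmax(stats::rnorm(n, 65, 10), 30), 90))
  sex <- sample(c("female", "male"), n, replace = TRUE)
  ancestry <- sample(c("EAS", "EUR", "AFR"), n, replace = TRUE,
                     prob = c(0.45, 0.45, 0.10))
  histology <- sample(c("LUAD", "LUSC", "carcinoid", "other"), n,
                      replace = TRUE, prob = c(0.84, 0.06, 0.05, 0.05))
  stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                  prob = c(0.45, 0.2, 0.2, 0.15))
  smoking <- sample(c("LCINS", "LCSS"), n, replace = TRUE, prob = c(0.72, 0.28))
  lambda0 <- 0.15  # baseline events per year; median OS ~4.6 years
  hz <- lambda0 * ifelse(has_ecdna, cfg$effect_hr_ecdna, 1)
  t_event <- stats::rexp(n, hz)
  cr <- cfg$censoring_rate
  t_cens <- if (cr > 0) stats::rexp(n, lambda0 * cr / (1 - cr)) else rep(Inf, n)
  out <- data.frame(
    sample_id = truth$sample_id, is_wgd = truth$is_wgd, has_ecdna = has_ecdna,
    age = age, sex = sex, ancestry = ancestry, histology = histology,
    stage = stage, smoking = smoking,
    time = pmin(t_event, t_cens), event = as.integer(t_event <= t_cens),
    stringsAsFactors = FALSE)
  if ("purity" %in% names(truth)) out$purity <- truth$purity
  out
}

#' Simulate a full synthetic cohort with ground truth
#'
#' Orchestrates the generator end to end. Per-sample event flags (WGD, ecDNA,
#' BFB, linear amplification, chromothripsis) are drawn first — ecDNA via the
#' logistic model of [simulate_clinical()] so the injected WGD-to-ecDNA odds
#' ratio holds — and the genomic profiles are then built to match: every
#' ecDNA-positive sample receives >= 1 cyclic amplicon, BFB samples a
#' foldback amplicon, linear samples an SV-free amplification, chromothripsis
#' samples a clustered-SV event with oscillating copy number.
#'
#' @param cfg A [simulation_config()].
#' @param amplicon_cn_range Range of injected amplicon total copy numbers.
#' @param amplicon_len_range Range of injected amplicon lengths (bp).
#' @param chromothripsis_sv_range Range (inclusive) of cluster sizes for
#'   injected chromothripsis events.
#' @return A `sim_cohort` list: `cfg`, `profiles` (list of `sim_profile`),
#'   `clinical` (data frame), `truth` (data frame of per-sample flags and
#'   injected loci in `amplicon_truth`).
#' @export
simulate_cohort <- function(cfg,
                            amplicon_cn_range = c(8, 40),
                            amplicon_len_range = c(0.5e6, 2e6),
                            chromothripsis_sv_range = c(10L, 16L)) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$rng_seed)
  n <- cfg$n_samples
  sample_id <- sprintf("S%04d", seq_len(n))
  is_wgd <- stats::runif(n) < cfg$wgd_fraction
  purity <- stats::runif(n, cfg$purity_range[1], cfg$purity_range[2])
  clinical <- simulate_clinical(
    data.frame(sample_id = sample_id, is_wgd = is_wgd, purity = purity,
               stringsAsFactors = FALSE), cfg)
  has_ecdna <- clinical$has_ecdna
  has_bfb <- stats::runif(n) < cfg$bfb_fraction
  has_linear <- stats::runif(n) < cfg$linear_fraction
  has_ct <- stats::runif(n) < cfg$chromothripsis_fraction
  profiles <- vector("list", n)
  amp_truth <- list()
  for (i in seq_len(n)) {
    prof <- simulate_segment_profile(cfg, i, is_wgd = is_wgd[i],
                                     purity = purity[i])
    # reserve distinct chromosomes per event so injections never collide
    chroms <- sample(cfg$genome$chrom, 4)
    kinds <- c(if (has_ecdna[i]) "cyclic", if (has_bfb[i]) "foldback",
               if (has_linear[i]) "linear")
    for (k in seq_along(kinds)) {
      chrom <- chroms[k]
      len <- stats::runif(1, amplicon_len_range[1], amplicon_len_range[2])
      cl <- cfg$genome$length[match(chrom, cfg$genome$chrom)]
      start <- round(stats::runif(1, 0, cl - len))
      end <- round(start + len)
      cn <- stats::runif(1, amplicon_cn_range[1], amplicon_cn_range[2])
      prof <- inject_focal_amplicon(prof, chrom, start, end, cn,
                                    kind = kinds[k])
      amp_truth[[length(amp_truth) + 1L]] <- data.frame(
        sample_id = sample_id[i], chrom = chrom, start = start, end = end,
        cn = cn, kind = kinds[k], stringsAsFactors = FALSE)
    }
    if (has_ct[i]) {
      n_sv <- sample(seq(chromothripsis_sv_range[1],
                         chromothripsis_sv_range[2]), 1)
      prof <- inject_chromothripsis(prof, chroms[4], n_sv)
    }
    profiles[[i]] <- prof
  }
  # telomere read groups (tumor + matched normal) with a known log2 ratio
  tl_f_normal <- 0.001 * exp(stats::rnorm(n, 0, 0.2))
  tl_ratio <- exp(stats::rnorm(n, 0, 0.4))
  telomere <- do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(c("tumor", "normal"), function(tissue) {
      f <- if (tissue == "tumor") tl_f_normal[i] * tl_ratio[i] else
        tl_f_normal[i]
      ng <- sample(2:4, 1)
      nr <- round(stats::runif(ng, 5e4, 15e4))
      data.frame(sample_id = sample_id[i], tissue = tissue,
                 group_id = paste0("rg", seq_len(ng)), n_reads = nr,
                 n_telomeric = stats::rbinom(ng, nr, f),
                 stringsAsFactors = FALSE)
    }))
  }))
  # read depths encoding a known tumor-cell mitochondrial copy number
  mt_cn_true <- 500 * exp(stats::rnorm(n, 0, 0.3))
  m_normal <- 200 * exp(stats::rnorm(n, 0, 0.2))
  depth_nuc_t <- 30 * exp(stats::rnorm(n, 0, 0.1))
  depth_nuc_n <- 30 * exp(stats::rnorm(n, 0, 0.1))
  ploidy <- vapply(profiles, function(p) p$ploidy, numeric(1))
  pe <- purity * ploidy + 2 * (1 - purity)
  m_mix <- purity * mt_cn_true + (1 - purity) * m_normal
  depths <- data.frame(
    sample_id = sample_id,
    depth_mt_t = m_mix / pe * depth_nuc_t, depth_nuc_t = depth_nuc_t,
    depth_mt_n = m_normal / 2 * depth_nuc_n, depth_nuc_n = depth_nuc_n,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    sample_id = sample_id, is_wgd = is_wgd, has_ecdna = has_ecdna,
    has_bfb = has_bfb, has_linear = has_linear, has_chromothripsis = has_ct,
    purity = purity, ploidy = ploidy,
    tl_log2_ratio_true = log2(tl_ratio), mt_cn_true = mt_cn_true,
    stringsAsFactors = FALSE)
  structure(list(cfg = cfg, profiles = profiles, clinical = clinical,
                 truth = truth, telomere = telomere, depths = depths,
                 amplicon_truth = if (length(amp_truth))
                   do.call(rbind, amp_truth) else NULL),
            class = "sim_cohort")
}

#' Write a simulated cohort to disk
#'
#' Writes, per sample, `<id>.segments.tsv` (chrom, start, end, logR,
#' major_cn, minor_cn) and `<id>.sv.bedpe` (BEDPE columns; 0-based
#' half-open), plus cohort-level `samples.tsv` (purity, ploidy, covariates,
#' survival) and `truth.json` (ground-truth flags and injected amplicon
#' loci).
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (prof in cohort$profiles) {
    seg <- prof$segments[, c("chrom", "start", "end", "logR", "major_cn",
                             "minor_cn")]
    utils::write.table(
      seg, file.path(dir, paste0(prof$sample_id, ".segments.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    sv <- prof$sv
    bedpe <- data.frame(
      chrom1 = sv$chrom1, start1 = sv$pos1, end1 = sv$pos1 + 1,
      chrom2 = sv$chrom2, start2 = sv$pos2, end2 = sv$pos2 + 1,
      name = if (nrow(sv)) sprintf("sv%03d", seq_len(nrow(sv))) else character(),
      score = if (nrow(sv)) rep(".", nrow(sv)) else character(),
      strand1 = sv$strand1, strand2 = sv$strand2, svtype = sv$svtype,
      stringsAsFactors = FALSE)
    utils::write.table(
      bedpe, file.path(dir, paste0(prof$sample_id, ".sv.bedpe")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(cohort$telomere,
                     file.path(dir, "telomere_readgroups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$depths, file.path(dir, "depths.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  clin <- cohort$clinical[, setdiff(names(cohort$clinical), "purity")]
  samples <- merge(cohort$truth[, c("sample_id", "purity", "ploidy")],
                   clin, by = "sample_id")
  samples <- samples[order(samples$sample_id), ]
  utils::write.table(samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(samples = cohort$truth, amplicons = cohort$amplicon_truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a per-sample segment table
#'
#' @param path Path to a `segments.tsv` written by [write_cohort()].
#' @return Data frame with `chrom`, `start`, `end`, `logR`, `major_cn`,
#'   `minor_cn`.
#' @export
read_segments <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a BEDPE-like structural variant table
#'
#' @param path Path to a `sv.bedpe` written by [write_cohort()].
#' @return Data frame with `chrom1`, `pos1`, `strand1`, `chrom2`, `pos2`,
#'   `strand2`, `svtype` (breakend positions taken from start1/start2).
#' @export
read_bedpe <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(chrom1 = x$chrom1, pos1 = x$start1, strand1 = x$strand1,
             chrom2 = x$chrom2, pos2 = x$start2, strand2 = x$strand2,
             svtype = x$svtype, stringsAsFactors = FALSE)
}
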