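#' Configuration for the synthetic cohort generator
#'
#' Bundles the knobs of the cohort simulator: cohort size, tumor purity range,
#' prevalences of whole-genome doubling (WGD), ecDNA, breakage-fusion-bridge
#' (BFB), linear focal amplification and chromothripsis, segment-level logR
#' noise, the genome model, and the injected association/survival effect
#' sizes.
#'
#' Defaults describe a lung-cancer-like whole-genome cohort: ecDNA prevalence
#' 0.19, WGD prevalence 0.4, chromothripsis prevalence 0.3, purities 0.2-0.9,
#' a WGD-to-ecDNA odds ratio of 4.0 and an ecDNA hazard ratio of 2.17.
#' `logr_noise_sd` is the standard deviation of Gaussian noise on
#' segment-level logR (post-segmentation segment means are averages over many
#' bins, hence small noise). The toy genome is 22 autosomes of 10 Mb each;
#' real chromosome lengths can be supplied via `genome`.
#'
#' @param n_samples Number of tumors to simulate.
#' @param purity_range Length-2 vector, lower/upper tumor purity, in (0, 1].
#' @param wgd_fraction Fraction of samples with whole-genome doubling.
#' @param ecdna_fraction Marginal fraction of ecDNA-positive samples.
#' @param bfb_fraction Fraction of samples with a BFB amplicon.
#' @param linear_fraction Fraction of samples with a linear (SV-free) focal
#'   amplification.
#' @param chromothripsis_fraction Fraction of samples with a chromothripsis
#'   event.
#' @param logr_noise_sd Standard deviation of Gaussian noise added to each
#'   segment's logR.
#' @param genome Data frame with columns `chrom`, `length` (bp).
#' @param effect_or_wgd_ecdna Odds ratio of WGD on ecDNA presence (> 0).
#' @param effect_hr_ecdna Hazard ratio of ecDNA on overall survival (> 0).
#' @param censoring_rate Target fraction of censored survival times.
#' @param rng_seed Integer seed; all randomness in the generator derives
#'   from it.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_samples = 200,
                              purity_range = c(0.2, 0.9),
                              wgd_fraction = 0.4,
                              ecdna_fraction = 0.19,
                              bfb_fraction = 0.10,
                              linear_fraction = 0.15,
                              chromothripsis_fraction = 0.30,
                              logr_noise_sd = 0.01,
                              genome = toy_genome(),
                              effect_or_wgd_ecdna = 4.0,
                              effect_hr_ecdna = 2.17,
                              censoring_rate = 0.30,
                              rng_seed = 1L) {
  fracs <- c(wgd = wgd_fraction, ecdna = ecdna_fraction, bfb = bfb_fraction,
             linear = linear_fraction, chromothripsis = chromothripsis_fraction,
             censoring = censoring_rate)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (length(purity_range) != 2L || purity_range[1] > purity_range[2] ||
      purity_range[1] <= 0 || purity_range[2] > 1) {
    stop("purity_range must be an increasing pair inside (0, 1]")
  }
  if (logr_noise_sd < 0) stop("logr_noise_sd must be non-negative")
  if (effect_or_wgd_ecdna <= 0 || effect_hr_ecdna <= 0) {
    stop("effect sizes must be positive")
  }
  stopifnot(all(c("chrom", "length") %in% names(genome)))
  structure(list(
    n_samples = as.integer(n_samples), purity_range = purity_range,
    wgd_fraction = wgd_fraction, ecdna_fraction = ecdna_fraction,
    bfb_fraction = bfb_fraction, linear_fraction = linear_fraction,
    chromothripsis_fraction = chromothripsis_fraction,
    logr_noise_sd = logr_noise_sd, genome = genome,
    effect_or_wgd_ecdna = effect_or_wgd_ecdna,
    effect_hr_ecdna = effect_hr_ecdna,
    censoring_rate = censoring_rate, rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

#' Toy genome: 22 autosomes of 10 Mb
#'
#' @param n_chrom Number of autosomes.
#' @param chrom_length Length of each, in bp.
#' @return Data frame with `chrom`, `length`.
#' @export
toy_genome <- function(n_chrom = 22L, chrom_length = 10e6) {
  data.frame(chrom = paste0("chr", seq_len(n_chrom)),
             length = rep(chrom_length, n_chrom),
             stringsAsFactors = FALSE)
}

# empty BEDPE-like SV table with the column layout used throughout
empty_sv_table <- function() {
  data.frame(chrom1 = character(), pos1 = numeric(), strand1 = character(),
             chrom2 = character(), pos2 = numeric(), strand2 = character(),
             svtype = character(), stringsAsFactors = FALSE)
}

# recompute ploidy (length-weighted mean true TCN) and logR for a profile
refresh_profile <- function(profile) {
  seg <- profile$segments
  len <- seg$end - seg$start
  profile$ploidy <- sum(len * seg$true_tcn) / sum(len)
  model <- ploidy_model(profile$purity, profile$ploidy)
  seg$logR <- expected_logr(seg$true_tcn, model) + seg$noise
  profile$segments <- seg
  profile
}

#' Simulate one sample's copy-number segment profile
#'
#' Tiles every chromosome of the configured genome with segments (no gaps or
#' overlaps), assigns the baseline tumor copy number (total 2, major/minor
#' 1/1; doubled under WGD), draws the tumor purity, and emits the logR each
#' segment would show under the purity/ploidy dilution model
#' `logR = log2((rho * TCN + 2 * (1 - rho)) / psi) + N(0, logr_noise_sd)`,
#' where the recorded ploidy `psi` is the length-weighted mean of the true
#' total copy number.
#'
#' All randomness derives from `cfg$rng_seed` and `sample_idx`, so profiles
#' are reproducible per sample regardless of generation order.
#'
#' @param cfg A [simulation_config()].
#' @param sample_idx Sample index (1-based), used to derive the sample seed.
#' @param is_wgd Whole-genome doubled baseline? If `NULL`, drawn from
#'   `cfg$wgd_fraction`.
#' @param purity Tumor purity; if `NULL`, drawn uniformly from
#'   `cfg$purity_range`.
#' @return A `sim_profile` list: `sample_id`, `purity`, `ploidy`, `is_wgd`,
#'   `segments` (chrom, start, end, true_tcn, major_cn, minor_cn, noise,
#'   logR), `sv` (BEDPE-like), `genome`.
#' @export
simulate_segment_profile <- function(cfg, sample_idx, is_wgd = NULL,
                                     purity = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  seed <- (cfg$rng_seed + 104729L * as.integer(sample_idx)) %% .Machine$integer.max
  set.seed(seed)
  if (is.null(is_wgd)) is_wgd <- stats::runif(1) < cfg$wgd_fraction
  if (is.null(purity)) {
    purity <- stats::runif(1, cfg$purity_range[1], cfg$purity_range[2])
  }
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
  base_major <- if (is_wgd) 2L else 1L
  segs <- do.call(rbind, lapply(seq_len(nrow(cfg$genome)), function(i) {
    chrom <- cfg$genome$chrom[i]
    len <- cfg$genome$length[i]
    n_break <- stats::rpois(1, 3)
    brk <- sort(unique(round(stats::runif(n_break, 1, len - 1))))
    bounds <- c(0, brk, len)
    data.frame(chrom = chrom, start = bounds[-length(bounds)],
               end = bounds[-1], stringsAsFactors = FALSE)
  }))
  segs$true_tcn <- as.numeric(2L * base_major)
  segs$major_cn <- base_major
  segs$minor_cn <- base_major
  gained_chr <- character(0)
  if (is_wgd) {
    # post-doubling copy-neutral allelic imbalance (3+1) over ~70% of the
    # genome (by length), assigned chromosome-wise: the major allele reaches
    # 3 there while total copy number stays at 4
    ord_chr <- sample(cfg$genome$chrom)
    cum <- cumsum(cfg$genome$length[match(ord_chr, cfg$genome$chrom)])
    gained_chr <- ord_chr[seq_len(which(cum >= 0.7 *
                                          sum(cfg$genome$length))[1])]
    gain <- segs$chrom %in% gained_chr
    segs$major_cn[gain] <- segs$major_cn[gain] + 1L
    segs$minor_cn[gain] <- segs$minor_cn[gain] - 1L
  }
  segs$noise <- stats::rnorm(nrow(segs), 0, cfg$logr_noise_sd)
  profile <- list(sample_id = sprintf("S%04d", sample_idx), purity = purity,
                  ploidy = NA_real_, is_wgd = is_wgd, segments = segs,
                  sv = empty_sv_table(), genome = cfg$genome,
                  gained_chr = if (is_wgd) gained_chr else character(0),
                  noise_sd = cfg$logr_noise_sd,
                  truth_chromothripsis = NULL)
  class(profile) <- "sim_profile"
  refresh_profile(profile)
}

# split segments so that `pos` on `chrom` is a segment boundary
split_segments_at <- function(segs, chrom, pos) {
  hit <- which(segs$chrom == chrom & segs$start < pos & segs$end > pos)
  if (length(hit) == 0L) return(segs)
  i <- hit[1]
  left <- segs[i, ]; right <- segs[i, ]
  left$end <- pos; right$start <- pos
  out <- rbind(segs[seq_len(i - 1), ], left, right,
               segs[seq_len(nrow(segs)) > i, ])
  rownames(out) <- NULL
  out
}

#' Inject a focal amplification into a simulated profile
#'
#' Raises the true total copy number to `cn` over `locus` and adds the
#' structural variants characteristic of the amplification mechanism:
#' `"cyclic"` adds one head-to-tail (cycle-closing, duplication-like) junction
#' joining the locus end back to its start, the hallmark of a circular ecDNA;
#' `"foldback"` adds two closely spaced head-to-head inversion breakend pairs
#' at the right boundary, as in breakage-fusion-bridge; `"linear"` adds no SV.
#' The profile's ploidy and all segment logR values are recomputed under the
#' forward dilution model.
#'
#' @param profile A `sim_profile`.
#' @param chrom,start,end Locus (0-based half-open), within one chromosome.
#' @param cn New true total copy number on the locus (above baseline).
#' @param kind One of `"cyclic"`, `"foldback"`, `"linear"`.
#' @return The updated `sim_profile`.
#' @export
inject_focal_amplicon <- function(profile, chrom, start, end, cn,
                                  kind = c("cyclic", "foldback", "linear")) {
  kind <- match.arg(kind)
  gi <- match(chrom, profile$genome$chrom)
  if (is.na(gi) || start < 0 || end > profile$genome$length[gi] || start >= end) {
    stop("amplicon locus outside the genome")
  }
  segs <- split_segments_at(profile$segments, chrom, start)
  segs <- split_segments_at(segs, chrom, end)
  in_locus <- segs$chrom == chrom & segs$start >= start & segs$end <= end
  if (any(segs$true_tcn[in_locus] >= cn)) {
    stop("amplicon copy number must exceed the local baseline")
  }
  segs$major_cn[in_locus] <- round(cn) - segs$minor_cn[in_locus]
  segs$true_tcn[in_locus] <- cn
  profile$segments <- segs
  if (kind == "cyclic") {
    profile$sv <- rbind(profile$sv, data.frame(
      chrom1 = chrom, pos1 = start, strand1 = "-",
      chrom2 = chrom, pos2 = end, strand2 = "+",
      svtype = "DUP", stringsAsFactors = FALSE))
  } else if (kind == "foldback") {
    fb <- data.frame(
      chrom1 = chrom, pos1 = c(end - 20e3, end - 12e3), strand1 = "+",
      chrom2 = chrom, pos2 = c(end - 10e3, end - 2e3), strand2 = "+",
      svtype = "h2hINV", stringsAsFactors = FALSE)
    profile$sv <- rbind(profile$sv, fb)
  }
  refresh_profile(profile)
}

#' Inject a chromothripsis event into a simulated profile
#'
#' Places `n_sv` intrachromosomal structural variants in a confined window
#' with type drawn uniformly from DUP/DEL/h2hINV/t2tINV, and rewrites the
#' window's copy-number profile to oscillate between exactly two states
#' (baseline and baseline + 1), giving `n_sv` state switches across
#' `n_sv + 1` oscillating segments.
#'
#' @param profile A `sim_profile`.
#' @param chrom Chromosome for the event.
#' @param n_sv Number of clustered SVs (>= 1).
#' @param window_len Width of the shattered window in bp (default 3 Mb).
#' @return The updated `sim_profile`.
#' @export
inject_chromothripsis <- function(profile, chrom, n_sv, window_len = 3e6) {
  if (n_sv < 1) stop("n_sv must be >= 1")
  gi <- match(chrom, profile$genome$chrom)
  if (is.na(gi)) stop("chromosome absent from the genome")
  chrom_len <- profile$genome$length[gi]
  window_len <- min(window_len, chrom_len)
  w_start <- round(stats::runif(1, 0, chrom_len - window_len))
  w_end <- w_start + window_len
  segs <- split_segments_at(profile$segments, chrom, w_start)
  segs <- split_segments_at(segs, chrom, w_end)
  in_win <- which(segs$chrom == chrom & segs$start >= w_start & segs$end <= w_end)
  base <- min(segs$true_tcn[in_win])
  base_minor <- min(segs$minor_cn[in_win])
  # rebuild the window as n_sv + 1 equal-width segments oscillating between
  # the retained state and a one-copy loss (shattered fragments are lost)
  bounds <- round(seq(w_start, w_end, length.out = n_sv + 2))
  osc <- data.frame(chrom = chrom, start = bounds[-length(bounds)],
                    end = bounds[-1], stringsAsFactors = FALSE)
  osc$true_tcn <- pmax(base - rep_len(c(0, 1), nrow(osc)), 0)
  osc$minor_cn <- pmax(base_minor - rep_len(c(0, 1), nrow(osc)), 0)
  osc$major_cn <- round(osc$true_tcn) - osc$minor_cn
  osc$noise <- stats::rnorm(nrow(osc), 0, profile$noise_sd)
  osc$logR <- NA_real_
  keep <- segs[-in_win, ]
  segs <- rbind(keep, osc[, names(keep)])
  segs <- segs[order(segs$chrom, segs$start), ]
  rownames(segs) <- NULL
  profile$segments <- segs
  p1 <- round(stats::runif(n_sv, w_start, w_end))
  p2 <- round(stats::runif(n_sv, w_start, w_end))
  lo <- pmin(p1, p2); hi <- pmax(p1, p2)
  type <- sample(c("DUP", "DEL", "h2hINV", "t2tINV"), n_sv, replace = TRUE)
  strands <- list(DUP = c("-", "+"), DEL = c("+", "-"),
                  h2hINV = c("+", "+"), t2tINV = c("-", "-"))
  sv <- data.frame(
    chrom1 = chrom, pos1 = lo,
    strand1 = vapply(type, function(t) strands[[t]][1], character(1)),
    chrom2 = chrom, pos2 = hi,
    strand2 = vapply(type, function(t) strands[[t]][2], character(1)),
    svtype = type, stringsAsFactors = FALSE)
  profile$sv <- rbind(profile$sv, sv)
  profile$truth_chromothripsis <- rbind(
    profile$truth_chromothripsis,
    data.frame(chrom = chrom, start = w_start, end = w_end, n_sv = n_sv))
  refresh_profile(profile)
}
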