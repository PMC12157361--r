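# Genome instability metrics: whole-genome doubling, wGII, telomere length
# tumor/normal ratio, and purity/ploidy-adjusted mitochondrial copy number.

#' Call whole-genome doubling
#'
#' A sample is whole-genome doubled when the major allele copy number is at
#' least `major_cn_min` over more than `frac_min` of the genome. The fraction
#' is length-weighted by default, which makes the call invariant to how the
#' genome was cut into segments; `weight = "count"` reproduces a plain
#' segment-count reading.
#'
#' @param segments Data frame with `chrom`, `start`, `end`, `major_cn`.
#' @param major_cn_min Major copy number cutoff (default 3).
#' @param frac_min Genome fraction that must exceed the cutoff; strict
#'   inequality (default 0.5).
#' @param weight `"length"` (default) or `"count"`.
#' @return Logical flag.
#' @export
call_wgd <- function(segments, major_cn_min = 3L, frac_min = 0.5,
                     weight = c("length", "count")) {
  weight <- match.arg(weight)
  if (nrow(segments) == 0L) stop("empty segment list")
  stopifnot(all(c("major_cn") %in% names(segments)))
  hi <- segments$major_cn >= major_cn_min
  frac <- if (weight == "length") {
    len <- segments$end - segments$start
    sum(len[hi]) / sum(len)
  } else {
    mean(hi)
  }
  frac > frac_min
}

#' Weighted genome instability index (wGII)
#'
#' The overall ploidy is the length-weighted average copy number of all
#' segments. Per autosome, the aberrant fraction is the length-weighted
#' fraction of bases whose rounded total copy number differs from the rounded
#' ploidy; these 22 per-chromosome fractions are summed and divided by 22.
#' Autosomes with no segments contribute 0.
#'
#' @param segments Data frame with `chrom`, `start`, `end`, `tcn`.
#' @param autosomes Character vector of autosome names (default the 22
#'   `chr1`..`chr22`).
#' @return List: `wgii` (in \[0, 1\]) and `ploidy_lw` (length-weighted
#'   ploidy).
#' @export
compute_wgii <- function(segments, autosomes = paste0("chr", 1:22)) {
  stopifnot(all(c("chrom", "start", "end", "tcn") %in% names(segments)))
  seg <- segments[segments$chrom %in% autosomes, , drop = FALSE]
  if (nrow(seg) == 0L) stop("no segments on the requested autosomes")
  len <- seg$end - seg$start
  ploidy_lw <- sum(len * seg$tcn) / sum(len)
  ref <- round(ploidy_lw)
  aberrant <- round(seg$tcn) != ref
  per_chr <- vapply(autosomes, function(ch) {
    i <- seg$chrom == ch
    if (!any(i)) return(0)
    sum(len[i & aberrant]) / sum(len[i])
  }, numeric(1))
  list(wgii = sum(per_chr) / length(autosomes), ploidy_lw = ploidy_lw)
}

#' Count telomeric reads
#'
#' A read is telomeric when it contains at least `min_repeats`
#' non-overlapping occurrences of the telomeric repeat TTAGGG or of its
#' reverse complement CCCTAA (case-insensitive).
#'
#' @param reads Character vector of read sequences.
#' @param min_repeats Repeat-count threshold (default 7).
#' @return Number of telomeric reads.
#' @export
count_telomeric_reads <- function(reads, min_repeats = 7L) {
  if (length(reads) == 0L) return(0L)
  count_motif <- function(seqs, motif) {
    vapply(gregexpr(motif, toupper(seqs), fixed = TRUE), function(m) {
      if (m[1] == -1L) 0L else length(m)
    }, integer(1))
  }
  sum(count_motif(reads, "TTAGGG") >= min_repeats |
        count_motif(reads, "CCCTAA") >= min_repeats)
}

#' Estimate sample telomere length from read groups
#'
#' Per read group, telomere length is `c * n_telomeric / n_reads`; the sample
#' estimate is the read-count-weighted mean over its read groups.
#'
#' @param groups Data frame with `n_reads`, `n_telomeric` (and optionally a
#'   precomputed `tl_kb` column, used as-is when present).
#' @param scale Scale constant `c` (default 1; cancels in tumor/normal
#'   ratios).
#' @return Weighted-mean telomere length.
#' @export
estimate_sample_tl <- function(groups, scale = 1) {
  stopifnot("n_reads" %in% names(groups))
  if (sum(groups$n_reads) <= 0) stop("zero total reads across read groups")
  tl <- if ("tl_kb" %in% names(groups)) groups$tl_kb else
    scale * groups$n_telomeric / groups$n_reads
  sum(groups$n_reads * tl) / sum(groups$n_reads)
}

#' Telomere length tumor/normal log2 ratio
#'
#' @param tumor_tl,normal_tl Positive telomere length estimates on a common
#'   scale.
#' @return `log2(tumor_tl / normal_tl)`.
#' @export
tl_log2_ratio <- function(tumor_tl, normal_tl) {
  if (any(tumor_tl <= 0) || any(normal_tl <= 0)) {
    stop("telomere lengths must be positive")
  }
  log2(tumor_tl / normal_tl)
}

#' Purity/ploidy-adjusted mitochondrial copy number
#'
#' The tumor sample's mitochondria-to-nuclear depth ratio `R_t` reflects a
#' mixture of tumor and normal cells. With mixture nuclear content
#' `Pe = rho * psi + 2 * (1 - rho)`, the mixture carries `M = R_t * Pe`
#' mitochondrial copies per cell; subtracting the normal contribution
#' (estimated from the matched normal as `M_n = 2 * depth_mt_n /
#' depth_nuc_n`) and dividing by purity yields the tumor-cell mitochondrial
#' copy number.
#'
#' @param depth_mt_t,depth_nuc_t Tumor mitochondrial and nuclear mean depths.
#' @param depth_mt_n,depth_nuc_n Matched-normal mitochondrial and nuclear
#'   mean depths.
#' @param model A [ploidy_model()].
#' @return Tumor-cell mitochondrial copy number (clamped at 0).
#' @export
mito_copy_number <- function(depth_mt_t, depth_nuc_t, depth_mt_n,
                             depth_nuc_n, model) {
  stopifnot(inherits(model, "ploidy_model"))
  if (any(c(depth_mt_t, depth_nuc_t, depth_mt_n, depth_nuc_n) <= 0)) {
    stop("depths must be positive")
  }
  rho <- model$purity; psi <- model$ploidy
  r_t <- depth_mt_t / depth_nuc_t
  pe <- rho * psi + 2 * (1 - rho)
  m_mix <- r_t * pe
  m_n <- 2 * depth_mt_n / depth_nuc_n
  max(0, (m_mix - (1 - rho) * m_n) / rho)
}
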