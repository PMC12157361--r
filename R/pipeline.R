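# End-to-end per-sample and cohort drivers tying the modules together.

#' Process one sample end to end
#'
#' Rescales copy number, calls seeds, decomposes and classifies amplicons,
#' applies the chromothripsis criteria, and computes instability metrics
#' (WGD, wGII) for a single sample.
#'
#' @param segments Data frame `chrom`, `start`, `end`, `logR`, `major_cn`,
#'   `minor_cn`.
#' @param model A [ploidy_model()].
#' @param svs BEDPE-like SV data frame.
#' @param genome Data frame `chrom`, `length`.
#' @param corrected Use purity/ploidy-corrected CN (default TRUE).
#' @param ... Passed to [amplicon_pipeline()].
#' @return List: `amplicons` (from [amplicon_pipeline()]), `chromothripsis`
#'   (call table), `is_wgd`, `wgii`, `ploidy_lw`, `ecdna_intervals`.
#' @export
process_sample <- function(segments, model, svs, genome, corrected = TRUE,
                           ...) {
  amp <- amplicon_pipeline(segments, model, svs, corrected = corrected, ...)
  ct <- call_chromothripsis(svs, amp$segments, genome)
  autos <- intersect(paste0("chr", 1:22), unique(segments$chrom))
  gii <- compute_wgii(amp$segments, autosomes = autos)
  ecdna_iv <- do.call(rbind, lapply(
    amp$amplicons[amp$classes == "ecDNA"], function(a) a$intervals))
  if (is.null(ecdna_iv)) {
    ecdna_iv <- data.frame(chrom = character(), start = numeric(),
                           end = numeric())
  }
  ov <- overlap_ecdna_chromothripsis(ecdna_iv, ct)
  list(amplicons = amp, chromothripsis = ct,
       is_wgd = call_wgd(segments), wgii = gii$wgii,
       ploidy_lw = gii$ploidy_lw, ecdna_intervals = ecdna_iv,
       ecdna_ct_overlap = ov)
}

#' Process a simulated cohort into a per-sample call table
#'
#' Runs [process_sample()] on every profile of a [simulate_cohort()] result
#' and returns one row per sample with the calls the association layer
#' consumes.
#'
#' @param cohort A `sim_cohort`.
#' @param corrected Use purity/ploidy-corrected CN (default TRUE).
#' @param ... Passed to [process_sample()].
#' @return Data frame: `sample_id`, `ecdna_called`, `ecdna_count`,
#'   `other_focal_called`, `chromothripsis_called`, `wgd_called`, `wgii`,
#'   `ecdna_ct_overlap`.
#' @export
process_cohort <- function(cohort, corrected = TRUE, ...) {
  stopifnot(inherits(cohort, "sim_cohort"))
  rows <- lapply(cohort$profiles, function(prof) {
    model <- ploidy_model(prof$purity, prof$ploidy)
    res <- process_sample(prof$segments, model, prof$sv, cohort$cfg$genome,
                          corrected = corrected, ...)
    cls <- res$amplicons$classes
    data.frame(
      sample_id = prof$sample_id,
      ecdna_called = res$amplicons$summary$ecdna_positive,
      ecdna_count = res$amplicons$summary$ecdna_count,
      other_focal_called = any(cls %in% c("BFB", "complex_noncyclic",
                                          "linear")),
      chromothripsis_called = any(res$chromothripsis$high_confidence),
      wgd_called = res$is_wgd, wgii = res$wgii,
      ecdna_ct_overlap = res$ecdna_ct_overlap$any_overlap,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
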