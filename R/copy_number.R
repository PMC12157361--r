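#' Purity/ploidy model for one sample
#'
#' Validates and bundles the tumor purity `rho` (fraction of tumor cells in
#' the sequenced sample, in (0, 1]) and tumor ploidy `psi` (average tumor-cell
#' genome copy number, > 0) used to rescale read-depth log-ratios into total
#' copy number.
#'
#' @param purity Tumor cell fraction, in (0, 1].
#' @param ploidy Average tumor-cell copy number, > 0.
#' @return An object of class `ploidy_model` (a named list with `purity`,
#'   `ploidy`).
#' @export
ploidy_model <- function(purity, ploidy) {
  if (!is.numeric(purity) || length(purity) != 1L || is.na(purity) ||
      purity <= 0 || purity > 1) {
    stop("invalid ploidy model: purity must be a single value in (0, 1]")
  }
  if (!is.numeric(ploidy) || length(ploidy) != 1L || is.na(ploidy) ||
      ploidy <= 0) {
    stop("invalid ploidy model: ploidy must be a single positive value")
  }
  structure(list(purity = purity, ploidy = ploidy), class = "ploidy_model")
}

#' @export
print.ploidy_model <- function(x, ...) {
  cat(sprintf("<ploidy_model> purity = %.3f, ploidy = %.3f\n",
              x$purity, x$ploidy))
  invisible(x)
}

#' Rescale total copy number for tumor purity and ploidy
#'
#' Converts a segment log-ratio of tumor to normal read depth (logR) into the
#' total copy number (TCN) of the tumor cells, removing the dilution by normal
#' (diploid) cells:
#'
#'   TCN = (psi * 2^logR - 2 * (1 - rho)) / rho
#'
#' where `rho` is the tumor purity and `psi` the tumor ploidy. Values that
#' come out negative (possible under read-depth noise at low purity) are
#' clamped to zero; the number of clamped values is attached as the
#' `"n_clamped"` attribute and reported with a warning.
#'
#' @param logr Numeric vector of log2 tumor/normal depth ratios.
#' @param model A [ploidy_model()].
#' @param warn Warn when clamping negatives (default TRUE).
#' @return Numeric vector of total copy numbers (>= 0), with attribute
#'   `n_clamped`.
#' @seealso [uncorrected_total_copy_number()] for the purity-1/ploidy-2
#'   special case.
#' @export
rescale_total_copy_number <- function(logr, model, warn = TRUE) {
  stopifnot(inherits(model, "ploidy_model"))
  raw <- (model$ploidy * 2^logr - 2 * (1 - model$purity)) / model$purity
  n_clamped <- sum(raw < 0, na.rm = TRUE)
  if (n_clamped > 0 && warn) {
    warning(sprintf("clamped %d negative rescaled copy number value(s) to 0",
                    n_clamped))
  }
  tcn <- pmax(raw, 0)
  attr(tcn, "n_clamped") <- n_clamped
  tcn
}

#' Uncorrected total copy number
#'
#' Total copy number under the default read-depth assumption of purity 1 and
#' ploidy 2 (`2 * 2^logR`), i.e. what a caller reports when it does not
#' correct for purity and ploidy.
#'
#' @param logr Numeric vector of log2 tumor/normal depth ratios.
#' @return Numeric vector `2 * 2^logr`.
#' @export
uncorrected_total_copy_number <- function(logr) {
  2 * 2^logr
}

#' Forward logR model
#'
#' The algebraic inverse of [rescale_total_copy_number()]: the logR emitted by
#' a read-depth caller for a segment of true tumor total copy number `tcn` in
#' a sample of purity `rho` and ploidy `psi` is
#' `log2((rho * tcn + 2 * (1 - rho)) / psi)`. Used by the cohort simulator.
#'
#' @param tcn True tumor total copy number (vector).
#' @param model A [ploidy_model()].
#' @return Numeric vector of logR values.
#' @export
expected_logr <- function(tcn, model) {
  stopifnot(inherits(model, "ploidy_model"))
  log2((model$purity * tcn + 2 * (1 - model$purity)) / model$ploidy)
}

#' Call amplicon seed regions from copy-number segments
#'
#' Identifies putative seed regions for amplicon reconstruction: maximal runs
#' of segments whose total copy number reaches `min_cn`, merged across gaps up
#' to `merge_gap`, and emitted when the merged span reaches `min_len`.
#' Defaults follow conventional amplicon-seeding practice (CN >= 4.5 over
#' >= 50 kb, merging across <= 300 kb).
#'
#' @param segments Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `tcn`; must be sorted by (chrom, start) and
#'   non-overlapping within each chromosome.
#' @param min_cn Copy-number threshold for a segment to seed (default 4.5).
#' @param min_len Minimum merged length in bp (default 50000).
#' @param merge_gap Maximum gap in bp across which amplified runs are merged
#'   (default 300000).
#' @return Data frame with columns `chrom`, `start`, `end`, `max_tcn`,
#'   ordered by (chrom, start).
#' @export
call_seed_regions <- function(segments, min_cn = 4.5, min_len = 50e3,
                              merge_gap = 300e3) {
  stopifnot(all(c("chrom", "start", "end", "tcn") %in% names(segments)))
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), max_tcn = numeric())
  if (nrow(segments) == 0L) return(empty)
  chrom <- factor(segments$chrom, levels = unique(segments$chrom))
  if (anyDuplicated(rle(as.integer(chrom))$values)) {
    stop("segments must be grouped by chromosome; refusing to sort silently")
  }
  if (any(tapply(segments$start, chrom, is.unsorted))) {
    stop("segments must be sorted by start within each chromosome; ",
         "refusing to sort silently")
  }
  by_chr <- split(segments, chrom)
  if (any(vapply(by_chr, function(s) any(s$start[-1] < s$end[-nrow(s)]),
                 logical(1)))) {
    stop("segments overlap within a chromosome")
  }
  out <- lapply(by_chr, function(s) {
    hi <- s[s$tcn >= min_cn, , drop = FALSE]
    if (nrow(hi) == 0L) return(NULL)
    # merge amplified segments whose gaps are <= merge_gap
    new_run <- c(TRUE, hi$start[-1] - hi$end[-nrow(hi)] > merge_gap)
    run <- cumsum(new_run)
    data.frame(
      chrom = hi$chrom[1],
      start = tapply(hi$start, run, min),
      end = tapply(hi$end, run, max),
      max_tcn = as.numeric(tapply(hi$tcn, run, max))
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out <- out[out$end - out$start >= min_len, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
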