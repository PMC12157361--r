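# ecDNA cargo annotation: which oncogenes, immunomodulatory genes, other
# genes, enhancers and promoters ride on each ecDNA, plus the six-criterion
# driver-mutation classifier.

#' Promoter regions (1 kb upstream of the TSS)
#'
#' For plus-strand genes the promoter is the 1000 bp upstream of the gene
#' start; for minus-strand genes, the 1000 bp downstream of the gene end.
#' Promoters are clipped at position 0 (and at the chromosome end when
#' chromosome lengths are supplied).
#'
#' @param genes Data frame with `name`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @param upstream Promoter width in bp (default 1000).
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   right-clipping.
#' @return Data frame `name`, `chrom`, `start`, `end`.
#' @export
promoter_regions <- function(genes, upstream = 1000, chrom_lengths = NULL) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(genes)))
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$start - upstream, genes$end)
  end <- ifelse(plus, genes$start, genes$end + upstream)
  start <- pmax(start, 0)
  if (!is.null(chrom_lengths)) {
    end <- pmin(end, chrom_lengths[genes$chrom])
  }
  out <- data.frame(name = genes$name, chrom = genes$chrom, start = start,
                    end = end, stringsAsFactors = FALSE)
  out[out$end > out$start, , drop = FALSE]
}

# fully-contained / any-overlap interval queries against a merged interval
# set (all 0-based half-open)
contained_in <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(logical(nrow(query)))
  }
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          subject$start <= query$start[i] & subject$end >= query$end[i])
  }, logical(1))
}

overlaps_any <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(logical(nrow(query)))
  }
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] & subject$end > query$start[i])
  }, logical(1))
}

#' Annotate ecDNA intervals with genetic cargo
#'
#' Genes and enhancers count as cargo only when 100% contained in the
#' (merged) ecDNA intervals; promoters count on any (>= 1 bp) overlap.
#' Containment is tested against the union of the ecDNA intervals, so
#' splitting an interval at an internal point does not change the result.
#'
#' @param ecdna Data frame of ecDNA intervals (`chrom`, `start`, `end`).
#' @param genes Data frame with `name`, `chrom`, `start`, `end`,
#'   `is_oncogene`, `is_immunomodulatory` (logical).
#' @param enhancers Data frame of enhancer intervals (`chrom`, `start`,
#'   `end`), or NULL.
#' @param promoters Data frame of promoter intervals (from
#'   [promoter_regions()]), or NULL.
#' @param gene_rule `"contained"` (default, mirrors the enhancer rule) or
#'   `"overlap"` to count partially overlapping genes.
#' @return List of flags: `has_oncogene`, `has_immunomodulatory`,
#'   `has_other_gene`, `has_enhancer`, `has_promoter`, `unknown`, plus
#'   `genes` (names of carried genes).
#' @export
annotate_ecdna <- function(ecdna, genes, enhancers = NULL, promoters = NULL,
                           gene_rule = c("contained", "overlap")) {
  gene_rule <- match.arg(gene_rule)
  merged <- merge_intervals(ecdna)
  g_hit <- if (is.null(genes) || nrow(genes) == 0L) logical(0) else {
    if (gene_rule == "contained") contained_in(genes, merged)
    else overlaps_any(genes, merged)
  }
  carried <- genes[g_hit, , drop = FALSE]
  has_onco <- any(carried$is_oncogene)
  has_immuno <- any(carried$is_immunomodulatory) && !has_onco
  has_other <- any(!carried$is_oncogene & !carried$is_immunomodulatory)
  has_enh <- !is.null(enhancers) && nrow(enhancers) > 0L &&
    any(contained_in(enhancers, merged))
  has_prom <- !is.null(promoters) && nrow(promoters) > 0L &&
    any(overlaps_any(promoters, merged))
  flags <- list(has_oncogene = isTRUE(has_onco),
                has_immunomodulatory = isTRUE(has_immuno),
                has_other_gene = isTRUE(has_other),
                has_enhancer = isTRUE(has_enh),
                has_promoter = isTRUE(has_prom))
  flags$unknown <- !any(unlist(flags))
  flags$genes <- carried$name
  flags
}

#' Classify ecDNA cargo into a single category
#'
#' Priority: oncogene > immunomodulatory > other gene > regulatory-only >
#' unknown. An ecDNA that carries an oncogene is never called
#' immunomodulatory (the immunomodulatory class requires the absence of an
#' oncogene).
#'
#' @param cargo Flag list from [annotate_ecdna()].
#' @return One of `"oncogene"`, `"immunomodulatory"`, `"other_gene"`,
#'   `"regulatory_only"`, `"unknown"`.
#' @export
classify_cargo <- function(cargo) {
  if (cargo$has_oncogene) return("oncogene")
  if (cargo$has_immunomodulatory) return("immunomodulatory")
  if (cargo$has_other_gene) return("other_gene")
  if (cargo$has_enhancer || cargo$has_promoter) return("regulatory_only")
  "unknown"
}

#' Classify a mutation as a potential driver
#'
#' A mutation is a potential driver when it meets one or more of:
#' (i) truncating in a tumor-suppressor gene; (ii) missense recurring in at
#' least 3 samples; (iii) boostDM score > 0.5; (iv) OncoKB label
#' "Oncogenic" or "Likely Oncogenic"; (v) flagged as a driver in the TCGA
#' MC3 set; (vi) missense labelled "likely pathogenic" in a tumor-suppressor
#' gene.
#'
#' @param consequence `"truncating"`, `"missense"`, or `"other"`.
#' @param is_tumor_suppressor Is the host gene a tumor suppressor?
#' @param recurrence_count Number of samples sharing the mutation (>= 1).
#' @param boostdm_score boostDM score, or NA.
#' @param oncokb_label OncoKB label, or NA.
#' @param mc3_flag Present in the MC3 driver set?
#' @param pathogenicity_label Clinical pathogenicity label, or NA.
#' @return Logical: potential driver?
#' @export
classify_driver_mutation <- function(consequence,
                                     is_tumor_suppressor = FALSE,
                                     recurrence_count = 1L,
                                     boostdm_score = NA_real_,
                                     oncokb_label = NA_character_,
                                     mc3_flag = FALSE,
                                     pathogenicity_label = NA_character_) {
  stopifnot(consequence %in% c("truncating", "missense", "other"),
            recurrence_count >= 1)
  crit <- c(
    consequence == "truncating" && isTRUE(is_tumor_suppressor),
    consequence == "missense" && recurrence_count >= 3,
    !is.na(boostdm_score) && boostdm_score > 0.5,
    !is.na(oncokb_label) && oncokb_label %in% c("Oncogenic",
                                                "Likely Oncogenic"),
    isTRUE(mc3_flag),
    consequence == "missense" && !is.na(pathogenicity_label) &&
      pathogenicity_label == "likely pathogenic" && isTRUE(is_tumor_suppressor)
  )
  any(crit)
}
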