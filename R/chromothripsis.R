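# High-confidence chromothripsis criteria applied to SV clusters and
# copy-number profiles. A cluster is called when (i) it contains more than 6
# intrachromosomal SVs (DUP/DEL/h2hINV/t2tINV), (ii) the copy number in its
# region oscillates between two states through more than 7 switches,
# (iii) breakpoints are enriched in the region (binomial tail p < 0.05), and
# (iv) fragment joins look random (chi-square goodness of fit p > 0.05)
# and/or the region participates in >= 4 inter-chromosomal rearrangements.

#' Cluster intrachromosomal SVs
#'
#' Single-linkage clustering of intrachromosomal breakends per chromosome:
#' SVs whose breakend footprints lie within `max_gap` of each other join the
#' same cluster. The cluster region spans min to max breakend.
#'
#' @param svs BEDPE-like data frame; only intrachromosomal, non-TRA records
#'   are clustered.
#' @param max_gap Single-linkage gap in bp (default 1e6).
#' @return Data frame: `chrom`, `start`, `end`, `n_sv`, `sv_idx` (list
#'   column of row indices into `svs`).
#' @export
cluster_intrachromosomal_svs <- function(svs, max_gap = 1e6) {
  keep <- which(svs$chrom1 == svs$chrom2 & svs$svtype != "TRA")
  if (length(keep) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_sv = integer()))
  }
  s <- svs[keep, , drop = FALSE]
  s$idx <- keep
  out <- lapply(split(s, s$chrom1), function(d) {
    m <- nrow(d)
    # union-find over SVs: breakends within max_gap link their SVs; the two
    # breakends of one SV are linked by construction
    parent <- seq_len(m)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    union_ <- function(i, j) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
    }
    pts <- data.frame(pos = c(d$pos1, d$pos2), sv = rep(seq_len(m), 2))
    pts <- pts[order(pts$pos), ]
    for (k in seq_len(nrow(pts) - 1L)) {
      if (nrow(pts) < 2L) break
      if (pts$pos[k + 1L] - pts$pos[k] <= max_gap) {
        union_(pts$sv[k], pts$sv[k + 1L])
      }
    }
    cl <- vapply(seq_len(m), find, integer(1))
    cl <- match(cl, unique(cl[order(pmin(d$pos1, d$pos2))]))
    lo <- pmin(d$pos1, d$pos2); hi <- pmax(d$pos1, d$pos2)
    res <- data.frame(chrom = d$chrom1[1],
                      start = as.numeric(tapply(lo, cl, min)),
                      end = as.numeric(tapply(hi, cl, max)),
                      n_sv = as.integer(tapply(cl, cl, length)))
    res$sv_idx <- unname(split(d$idx, cl))
    res <- res[order(res$start), , drop = FALSE]
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Count copy-number oscillations in a region
#'
#' Finds the longest run of consecutive segments whose rounded total copy
#' number alternates between exactly two values (no third state allowed
#' inside the run) and returns the number of state switches in that run.
#'
#' @param segments Ordered segment data frame with `tcn` (only the segments
#'   in the region of interest).
#' @return Integer switch count (0 for constant or empty input).
#' @export
count_oscillations <- function(segments) {
  cn <- round(segments$tcn)
  n <- length(cn)
  if (n < 2L) return(0L)
  best <- 0L
  i <- 1L
  while (i < n) {
    if (cn[i + 1L] == cn[i]) { i <- i + 1L; next }
    a <- cn[i]; b <- cn[i + 1L]
    j <- i + 1L
    # extend while strictly alternating between a and b
    while (j < n && cn[j + 1L] == (if (cn[j] == a) b else a) &&
           cn[j + 1L] != cn[j]) {
      j <- j + 1L
    }
    best <- max(best, j - i)
    i <- j
  }
  as.integer(best)
}

#' Breakpoint enrichment p-value
#'
#' One-sided binomial tail: the probability of seeing at least
#' `n_in_region` of `n_genome` breakpoints in a region of length
#' `region_len` when breakpoints land uniformly on a genome of length
#' `genome_len`.
#'
#' @param n_in_region Breakpoints observed in the region.
#' @param region_len Region length, bp.
#' @param n_genome Total breakpoints genome-wide.
#' @param genome_len Genome length, bp.
#' @return p-value in \[0, 1\].
#' @export
breakpoint_enrichment_pvalue <- function(n_in_region, region_len, n_genome,
                                         genome_len) {
  if (region_len <= 0 || genome_len <= 0) stop("lengths must be positive")
  if (n_in_region > n_genome) stop("n_in_region exceeds n_genome")
  p <- min(region_len / genome_len, 1)
  stats::pbinom(n_in_region - 1, n_genome, p, lower.tail = FALSE)
}

#' Fragment-join randomness p-value
#'
#' Chi-square goodness of fit of the four join-type counts
#' (DUP/DEL/h2hINV/t2tINV) against equal proportions, 3 degrees of freedom.
#' Large p means the joins look random, as expected under chromothripsis.
#'
#' @param type_counts Numeric vector of 4 counts (order-free).
#' @return p-value in \[0, 1\].
#' @export
join_randomness_pvalue <- function(type_counts) {
  if (length(type_counts) != 4L) stop("expected counts for 4 join types")
  total <- sum(type_counts)
  if (total < 1) stop("at least one join required")
  expected <- total / 4
  stat <- sum((type_counts - expected)^2 / expected)
  stats::pchisq(stat, df = 3, lower.tail = FALSE)
}

#' Apply the high-confidence chromothripsis criteria to one sample
#'
#' Clusters the sample's intrachromosomal SVs, evaluates the four criteria
#' per cluster, and flags clusters meeting all of: > 6 clustered SVs, > 7
#' copy-number oscillations, breakpoint enrichment p < 0.05, and (join
#' randomness p > 0.05 or >= 4 inter-chromosomal rearrangements touching the
#' region).
#'
#' @param svs BEDPE-like data frame for the sample.
#' @param segments Segment data frame with `chrom`, `start`, `end`, `tcn`.
#' @param genome Data frame with `chrom`, `length`.
#' @param max_gap Clustering gap (default 1e6).
#' @return Data frame, one row per cluster: region, `n_cluster_sv`,
#'   `n_oscillations`, `p_enrich`, `p_joins`, `n_interchrom`,
#'   `high_confidence`.
#' @export
call_chromothripsis <- function(svs, segments, genome, max_gap = 1e6) {
  clusters <- cluster_intrachromosomal_svs(svs, max_gap = max_gap)
  if (nrow(clusters) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_cluster_sv = integer(), n_oscillations = integer(),
                      p_enrich = numeric(), p_joins = numeric(),
                      n_interchrom = integer(), high_confidence = logical()))
  }
  genome_len <- sum(genome$length)
  # all breakends genome-wide (both ends of every record)
  n_genome <- 2L * nrow(svs)
  is_tra <- svs$svtype == "TRA" | svs$chrom1 != svs$chrom2
  res <- lapply(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    sub <- svs[cl$sv_idx[[1]], , drop = FALSE]
    type_counts <- vapply(c("DUP", "DEL", "h2hINV", "t2tINV"),
                          function(t) sum(sub$svtype == t), numeric(1))
    seg <- segments[segments$chrom == cl$chrom &
                      segments$start < cl$end & segments$end > cl$start, ,
                    drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    n_osc <- count_oscillations(seg)
    in_region <- function(chrom, pos) {
      chrom == cl$chrom & pos >= cl$start & pos <= cl$end
    }
    n_in <- sum(in_region(svs$chrom1, svs$pos1)) +
      sum(in_region(svs$chrom2, svs$pos2))
    p_enr <- breakpoint_enrichment_pvalue(n_in, cl$end - cl$start,
                                          n_genome, genome_len)
    p_join <- join_randomness_pvalue(type_counts)
    n_inter <- sum(is_tra & (in_region(svs$chrom1, svs$pos1) |
                               in_region(svs$chrom2, svs$pos2)))
    data.frame(chrom = cl$chrom, start = cl$start, end = cl$end,
               n_cluster_sv = cl$n_sv, n_oscillations = n_osc,
               p_enrich = p_enr, p_joins = p_join, n_interchrom = n_inter,
               high_confidence = cl$n_sv > 6 & n_osc > 7 & p_enr < 0.05 &
                 (p_join > 0.05 | n_inter >= 4))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Overlap between ecDNA intervals and chromothripsis regions
#'
#' @param ecdna Data frame of ecDNA intervals (`chrom`, `start`, `end`).
#' @param calls Data frame from [call_chromothripsis()]; only
#'   `high_confidence` rows are considered.
#' @return List: `any_overlap` (>= 1 bp intersection) and `overlap_bp`
#'   (total intersected bases).
#' @export
overlap_ecdna_chromothripsis <- function(ecdna, calls) {
  hc <- calls[calls$high_confidence, , drop = FALSE]
  if (nrow(ecdna) == 0L || nrow(hc) == 0L) {
    return(list(any_overlap = FALSE, overlap_bp = 0))
  }
  total <- 0
  for (i in seq_len(nrow(ecdna))) {
    for (j in seq_len(nrow(hc))) {
      if (ecdna$chrom[i] != hc$chrom[j]) next
      ov <- min(ecdna$end[i], hc$end[j]) - max(ecdna$start[i], hc$start[j])
      if (ov > 0) total <- total + ov
    }
  }
  list(any_overlap = total > 0, overlap_bp = total)
}
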