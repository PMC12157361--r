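# Breakpoint-graph amplicon classification.
#
# This is deliberately a simplified classifier, not a re-implementation of
# full amplicon reconstruction: seed regions are padded, SVs with both
# breakends inside padded seeds become discordant junctions, and each
# connected component is classified by an explicit decision rule (cycle ->
# ecDNA; foldback-dominated -> BFB; any SV -> complex non-cyclic; none ->
# linear). The graph is the standard oriented-endpoint construction: every
# genomic interval contributes a left and a right endpoint joined by a
# "sequence" edge; reference adjacency contributes concordant junctions;
# SVs contribute discordant junctions attached to the endpoint matching the
# breakend orientation ('+' = right end of the interval ending at the
# breakend, '-' = left end of the interval starting there). A circular
# structure is a closed walk alternating sequence and junction edges.

# merge intervals (0-based half-open) per chromosome
merge_intervals <- function(df, gap = 0) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  out <- lapply(split(df, df$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1, d$end),
                          min.gapwidth = gap + 1)
    data.frame(chrom = d$chrom[1], start = IRanges::start(ir) - 1,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Build a breakpoint graph over amplicon seed regions
#'
#' Pads each seed region by `pad`, admits structural variants with both
#' breakends inside padded seeds, splits the padded regions at every admitted
#' breakend, and assembles the oriented-endpoint graph (sequence, concordant
#' and discordant edges) used for amplicon decomposition and classification.
#'
#' @param seeds Data frame from [call_seed_regions()] (`chrom`, `start`,
#'   `end`).
#' @param svs BEDPE-like data frame (`chrom1`, `pos1`, `strand1`, `chrom2`,
#'   `pos2`, `strand2`, `svtype`).
#' @param segments CN-annotated segment data frame (`chrom`, `start`, `end`,
#'   `tcn`), used later for amplicon CN summaries.
#' @param pad Padding in bp around seeds when admitting SVs (default 1e5).
#' @return A `bp_graph` list: `intervals` (with `region_id`, `is_seed`),
#'   `junctions` (endpoint pairs with `type` and `sv_id`), `svs` (admitted
#'   SVs), `segments`, `component` (per-interval component id).
#' @export
build_breakpoint_graph <- function(seeds, svs, segments, pad = 100e3) {
  if (nrow(seeds) == 0L) {
    return(structure(list(intervals = NULL, junctions = NULL,
                          svs = svs[0, ], segments = segments,
                          component = integer(0)), class = "bp_graph"))
  }
  padded <- data.frame(chrom = seeds$chrom,
                       start = pmax(seeds$start - pad, 0),
                       end = seeds$end + pad, stringsAsFactors = FALSE)
  regions <- merge_intervals(padded)
  regions$region_id <- seq_len(nrow(regions))
  in_region <- function(chrom, pos) {
    hit <- regions$chrom == chrom & regions$start <= pos & pos <= regions$end
    if (any(hit)) regions$region_id[which(hit)[1]] else NA_integer_
  }
  if (nrow(svs) > 0L) {
    r1 <- mapply(in_region, svs$chrom1, svs$pos1)
    r2 <- mapply(in_region, svs$chrom2, svs$pos2)
    admitted <- svs[!is.na(r1) & !is.na(r2), , drop = FALSE]
  } else {
    admitted <- svs
  }
  if (nrow(admitted) > 0L) admitted$sv_id <- seq_len(nrow(admitted))
  # split regions at admitted breakend positions
  intervals <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    cuts <- numeric(0)
    if (nrow(admitted) > 0L) {
      cuts <- c(admitted$pos1[admitted$chrom1 == r$chrom],
                admitted$pos2[admitted$chrom2 == r$chrom])
      cuts <- cuts[cuts > r$start & cuts < r$end]
    }
    bounds <- sort(unique(c(r$start, cuts, r$end)))
    data.frame(chrom = r$chrom, start = bounds[-length(bounds)],
               end = bounds[-1], region_id = r$region_id,
               stringsAsFactors = FALSE)
  }))
  intervals$iid <- seq_len(nrow(intervals))
  intervals$is_seed <- vapply(seq_len(nrow(intervals)), function(i) {
    any(seeds$chrom == intervals$chrom[i] &
          seeds$start < intervals$end[i] & seeds$end > intervals$start[i])
  }, logical(1))
  # endpoint ids: left = 2*iid - 1, right = 2*iid
  left <- function(iid) 2L * iid - 1L
  right <- function(iid) 2L * iid
  # concordant junctions between reference-adjacent intervals
  conc <- do.call(rbind, lapply(split(intervals, intervals$region_id),
    function(iv) {
      if (nrow(iv) < 2L) return(NULL)
      data.frame(u = right(iv$iid[-nrow(iv)]), v = left(iv$iid[-1]),
                 type = "concordant", sv_id = NA_integer_)
    }))
  # discordant junctions from admitted SVs
  endpoint_at <- function(chrom, pos, strand) {
    if (strand == "+") {
      i <- which(intervals$chrom == chrom & intervals$end == pos)
      if (length(i)) right(intervals$iid[i[1]]) else NA_integer_
    } else {
      i <- which(intervals$chrom == chrom & intervals$start == pos)
      if (length(i)) left(intervals$iid[i[1]]) else NA_integer_
    }
  }
  disc <- NULL
  if (nrow(admitted) > 0L) {
    u <- mapply(endpoint_at, admitted$chrom1, admitted$pos1, admitted$strand1)
    v <- mapply(endpoint_at, admitted$chrom2, admitted$pos2, admitted$strand2)
    keep <- !is.na(u) & !is.na(v)
    if (any(keep)) {
      disc <- data.frame(u = u[keep], v = v[keep], type = "discordant",
                         sv_id = admitted$sv_id[keep])
    }
    admitted <- admitted[keep, , drop = FALSE]
  }
  junctions <- rbind(conc, disc)
  # undirected components over endpoints (sequence + junction edges)
  n_ep <- 2L * nrow(intervals)
  edges <- rbind(cbind(left(intervals$iid), right(intervals$iid)),
                 if (!is.null(junctions)) cbind(junctions$u, junctions$v))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_ep - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  component <- memb[right(intervals$iid)]
  structure(list(intervals = intervals, junctions = junctions,
                 svs = admitted, segments = segments,
                 component = as.integer(component)),
            class = "bp_graph")
}

# TRUE iff the endpoint set admits a closed walk alternating sequence and
# junction edges (i.e. a circular structure). Junction (a, b) yields directed
# arcs a -> partner(b) and b -> partner(a); concordant-only arcs follow the
# linear reference and are acyclic, so any directed cycle uses >= 1
# discordant junction.
alternating_cycle_exists <- function(junctions, n_intervals) {
  if (is.null(junctions) || nrow(junctions) == 0L) return(FALSE)
  partner <- function(e) ifelse(e %% 2L == 0L, e - 1L, e + 1L)
  arcs <- rbind(cbind(junctions$u, partner(junctions$v)),
                cbind(junctions$v, partner(junctions$u)))
  g <- igraph::graph_from_edgelist(arcs, directed = TRUE)
  !igraph::is_dag(g)
}

#' Decompose a breakpoint graph into amplicons
#'
#' One amplicon per connected component that contains at least one seed
#' interval; ids are assigned in order of the component's leftmost
#' coordinate.
#'
#' @param graph A `bp_graph` from [build_breakpoint_graph()].
#' @return List of `amplicon` lists: `id`, `intervals`, `sv_ids`,
#'   `has_cycle`, `n_sv`, `n_foldback`, `max_cn`, `median_cn`.
#' @export
decompose_amplicons <- function(graph) {
  stopifnot(inherits(graph, "bp_graph"))
  if (is.null(graph$intervals)) return(list())
  comp_ids <- unique(graph$component)
  amps <- list()
  for (cid in comp_ids) {
    iv <- graph$intervals[graph$component == cid, , drop = FALSE]
    if (!any(iv$is_seed)) next
    eps <- c(2L * iv$iid - 1L, 2L * iv$iid)
    jn <- graph$junctions
    if (is.null(jn)) {
      jn <- data.frame(u = integer(), v = integer(), type = character(),
                       sv_id = integer())
    }
    jn <- jn[jn$u %in% eps | jn$v %in% eps, , drop = FALSE]
    sv_ids <- sort(unique(jn$sv_id[jn$type == "discordant"]))
    svs <- graph$svs[graph$svs$sv_id %in% sv_ids, , drop = FALSE]
    n_fb <- if (nrow(svs)) sum(svs$svtype %in% c("h2hINV", "t2tINV") &
                                 svs$chrom1 == svs$chrom2 &
                                 abs(svs$pos2 - svs$pos1) <= 30e3) else 0L
    merged <- merge_intervals(iv)
    seg <- graph$segments
    cn <- unlist(lapply(seq_len(nrow(merged)), function(i) {
      hit <- seg$chrom == merged$chrom[i] & seg$start < merged$end[i] &
        seg$end > merged$start[i]
      seg$tcn[hit]
    }))
    amps[[length(amps) + 1L]] <- structure(list(
      intervals = merged, sv_ids = sv_ids,
      has_cycle = alternating_cycle_exists(jn, nrow(iv)),
      n_sv = length(sv_ids), n_foldback = n_fb,
      max_cn = if (length(cn)) max(cn) else NA_real_,
      median_cn = if (length(cn)) stats::median(cn) else NA_real_),
      class = "amplicon")
  }
  if (length(amps) == 0L) return(amps)
  first <- vapply(amps, function(a)
    paste(a$intervals$chrom[1], sprintf("%012.0f", a$intervals$start[1])),
    character(1))
  amps <- amps[order(first)]
  for (i in seq_along(amps)) amps[[i]]$id <- i
  amps
}

#' Classify one amplicon
#'
#' Decision rule: `ecDNA` if the component contains a cycle through at least
#' one discordant junction and its maximum copy number reaches
#' `min_ecdna_cn`; otherwise `BFB` if foldback SVs (head-to-head or
#' tail-to-tail inversions with breakend distance <= 30 kb) make up at least
#' `min_foldback_frac` of the component's SVs; otherwise `complex_noncyclic`
#' if any SV is present; otherwise `linear`. A component that is both cyclic
#' and foldback-rich is called ecDNA (ecDNA takes priority).
#'
#' @param amp An `amplicon` from [decompose_amplicons()].
#' @param min_ecdna_cn Minimum max CN for an ecDNA call (default 4.5).
#' @param min_foldback_frac Minimum foldback fraction for a BFB call
#'   (default 0.25).
#' @return One of `"ecDNA"`, `"BFB"`, `"complex_noncyclic"`, `"linear"`.
#' @export
classify_amplicon <- function(amp, min_ecdna_cn = 4.5,
                              min_foldback_frac = 0.25) {
  stopifnot(inherits(amp, "amplicon"))
  if (amp$has_cycle && !is.na(amp$max_cn) && amp$max_cn >= min_ecdna_cn) {
    return("ecDNA")
  }
  if (amp$n_sv > 0 && amp$n_foldback / amp$n_sv >= min_foldback_frac) {
    return("BFB")
  }
  if (amp$n_sv > 0) return("complex_noncyclic")
  "linear"
}

#' Summarize a sample's amplicons
#'
#' A sample is ecDNA-positive when it carries one or more ecDNA amplicons.
#'
#' @param amps List of classified amplicons, or a character vector of
#'   classes.
#' @param ... Passed to [classify_amplicon()] when `amps` are `amplicon`
#'   objects.
#' @return List: `ecdna_count`, `ecdna_positive`, `class_counts` (named
#'   integer vector over the four classes).
#' @export
summarize_sample <- function(amps, ...) {
  classes <- if (is.character(amps)) amps else
    vapply(amps, classify_amplicon, character(1), ...)
  lv <- c("ecDNA", "BFB", "complex_noncyclic", "linear")
  counts <- table(factor(classes, levels = lv))
  list(ecdna_count = as.integer(counts[["ecDNA"]]),
       ecdna_positive = counts[["ecDNA"]] >= 1,
       class_counts = stats::setNames(as.integer(counts), lv))
}

#' Run the per-sample amplicon pipeline
#'
#' Convenience wrapper: rescales copy number (corrected or uncorrected),
#' calls seeds, builds the breakpoint graph, decomposes and classifies
#' amplicons.
#'
#' @param segments Segment data frame with `chrom`, `start`, `end`, `logR`.
#' @param model A [ploidy_model()]; ignored when `corrected = FALSE`.
#' @param svs BEDPE-like SV data frame.
#' @param corrected Use purity/ploidy-corrected copy number (default TRUE).
#' @param min_cn,min_len,merge_gap Passed to [call_seed_regions()].
#' @param pad Passed to [build_breakpoint_graph()].
#' @param ... Passed to [classify_amplicon()].
#' @return List: `segments` (with `tcn`), `seeds`, `amplicons`, `classes`,
#'   `summary`.
#' @export
amplicon_pipeline <- function(segments, model, svs = empty_sv_table(),
                              corrected = TRUE, min_cn = 4.5, min_len = 50e3,
                              merge_gap = 300e3, pad = 100e3, ...) {
  segments$tcn <- if (corrected) {
    as.numeric(rescale_total_copy_number(segments$logR, model, warn = FALSE))
  } else {
    uncorrected_total_copy_number(segments$logR)
  }
  seeds <- call_seed_regions(segments, min_cn = min_cn, min_len = min_len,
                             merge_gap = merge_gap)
  graph <- build_breakpoint_graph(seeds, svs, segments, pad = pad)
  amps <- decompose_amplicons(graph)
  classes <- vapply(amps, classify_amplicon, character(1), ...)
  list(segments = segments, seeds = seeds, amplicons = amps,
       classes = classes, summary = summarize_sample(classes))
}
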