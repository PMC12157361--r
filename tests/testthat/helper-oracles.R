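# Independent brute-force oracles used to validate the package's algorithms
# on small inputs. These deliberately share no code with the implementation.

# segments data frame builder
seg_df <- function(chrom, start, end, tcn = NULL, major = NULL, minor = NULL,
                   logr = NULL) {
  d <- data.frame(chrom = chrom, start = start, end = end,
                  stringsAsFactors = FALSE)
  if (!is.null(tcn)) d$tcn <- tcn
  if (!is.null(major)) d$major_cn <- major
  if (!is.null(minor)) d$minor_cn <- minor
  if (!is.null(logr)) d$logR <- logr
  d
}

sv_df <- function(chrom1, pos1, strand1, chrom2, pos2, strand2, svtype) {
  data.frame(chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
             chrom2 = chrom2, pos2 = pos2, strand2 = strand2,
             svtype = svtype, stringsAsFactors = FALSE)
}

# longest alternating two-state run by exhaustive scan over all sub-runs
oracle_oscillations <- function(cn) {
  cn <- round(cn)
  n <- length(cn)
  best <- 0L
  if (n < 2L) return(best)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      run <- cn[i:j]
      vals <- unique(run)
      if (length(vals) != 2L) next
      if (all(diff(run) != 0)) best <- max(best, j - i)
    }
  }
  as.integer(best)
}

# transitive closure clustering of SVs: SVs are linked when any pair of
# their breakends lies within max_gap (each SV owns two breakends)
oracle_sv_clusters <- function(pos1, pos2, max_gap) {
  m <- length(pos1)
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      pi <- c(pos1[i], pos2[i]); pj <- c(pos1[j], pos2[j])
      adj[i, j] <- min(abs(outer(pi, pj, "-"))) <= max_gap
    }
  }
  reach <- adj
  for (k in seq_len(m)) {
    reach <- reach | (reach %*% reach > 0)
  }
  # canonical labels: smallest member index
  apply(reach, 1, function(r) min(which(r)))
}

# binomial upper tail by direct summation
oracle_binom_tail <- function(x, n, p) {
  if (x <= 0) return(1)
  sum(vapply(x:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k),
             numeric(1)))
}

# Fisher two-sided p by hypergeometric enumeration (tables with probability
# <= observed)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) stats::dhyper(x, m, n, k), numeric(1))
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exhaustive enumeration of closed alternating walks in an oriented-endpoint
# graph: junctions is a data.frame with endpoint ids u, v; partner of
# endpoint e is e+1 for odd e, e-1 for even e. Returns TRUE when a circular
# structure exists.
oracle_alternating_cycle <- function(junctions) {
  if (is.null(junctions) || nrow(junctions) == 0L) return(FALSE)
  partner <- function(e) if (e %% 2 == 0) e - 1L else e + 1L
  eps <- unique(c(junctions$u, junctions$v))
  found <- FALSE
  walk <- function(current, start, visited) {
    if (found) return()
    for (r in seq_len(nrow(junctions))) {
      uv <- c(junctions$u[r], junctions$v[r])
      if (!current %in% uv) next
      nxt_end <- if (current == uv[1]) uv[2] else uv[1]
      landing <- partner(nxt_end)        # traverse the next segment
      if (landing == start) { found <<- TRUE; return() }
      if (landing %in% visited) next
      walk(landing, start, c(visited, landing))
    }
  }
  for (s in eps) {
    walk(s, s, s)
    if (found) break
  }
  found
}

# Cox partial log-likelihood (no ties) for a single binary covariate
oracle_cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# flags for the six-clause driver disjunction, written out literally
oracle_driver <- function(consequence, tsg, rec, boost, oncokb, mc3, path) {
  c1 <- consequence == "truncating" && tsg
  c2 <- consequence == "missense" && rec >= 3
  c3 <- !is.na(boost) && boost > 0.5
  c4 <- !is.na(oncokb) && oncokb %in% c("Oncogenic", "Likely Oncogenic")
  c5 <- mc3
  c6 <- consequence == "missense" && !is.na(path) &&
    path == "likely pathogenic" && tsg
  c1 || c2 || c3 || c4 || c5 || c6
}
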