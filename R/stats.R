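# Association and survival layer: standard and Firth-penalized logistic
# regression, BH-FDR, Mann-Whitney, 2x2 odds ratios with exact tests, Cox
# proportional hazards, and the cohort-level association suite.

# build a design matrix (with intercept) from a covariate data frame,
# expanding factors/characters via model.matrix
design_matrix <- function(x) {
  x <- as.data.frame(x)
  stats::model.matrix(~ ., data = x)
}

logistic_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

#' Logistic regression with Wald inference
#'
#' Maximum-likelihood logistic regression (iteratively reweighted scoring via
#' `stats::glm`) with Wald 95% confidence intervals. Complete or
#' quasi-complete separation is detected (non-convergence or runaway
#' coefficients) and raised as an error pointing to the Firth variant.
#'
#' @param x Covariate data frame or matrix (no intercept column; factors
#'   allowed).
#' @param y Binary outcome (0/1 or logical).
#' @return Data frame: `term`, `log_odds`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p`.
#' @seealso [fit_firth_logistic()]
#' @export
fit_logistic <- function(x, y) {
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)))
  X <- design_matrix(x)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-8, maxit = 100)))
  beta <- fit$coefficients
  if (!fit$converged || any(abs(beta) > 15)) {
    stop("possible complete separation: logistic MLE did not stabilize; ",
         "consider fit_firth_logistic()")
  }
  w <- fit$weights
  cov <- solve(crossprod(X * sqrt(w)))
  se <- sqrt(diag(cov))
  z <- beta / se
  data.frame(term = colnames(X), log_odds = unname(beta),
             odds_ratio = unname(exp(beta)),
             ci_low = unname(exp(beta - stats::qnorm(0.975) * se)),
             ci_high = unname(exp(beta + stats::qnorm(0.975) * se)),
             p = unname(2 * stats::pnorm(-abs(z))),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Firth machinery ------------------------------------------------------------

firth_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  pi <- stats::plogis(eta)
  w <- pmax(pi * (1 - pi), 1e-12)
  info <- crossprod(X * sqrt(w))
  logistic_loglik(beta, X, y) + 0.5 * determinant(info)$modulus[1]
}

# one modified-score update restricted to `free` coefficients (all by
# default); returns the step direction
firth_step <- function(beta, X, y, free) {
  eta <- drop(X %*% beta)
  pi <- stats::plogis(eta)
  w <- pmax(pi * (1 - pi), 1e-12)
  info <- crossprod(X * sqrt(w))
  inv <- solve(info)
  h <- rowSums((X %*% inv) * X) * w       # hat diagonal
  ustar <- drop(crossprod(X, y - pi + h * (0.5 - pi)))
  delta <- rep(0, length(beta))
  delta[free] <- solve(info[free, free, drop = FALSE], ustar[free])
  list(delta = delta, score = ustar[free], info = info)
}

firth_maximize <- function(X, y, beta = rep(0, ncol(X)),
                           free = seq_len(ncol(X)), tol = 1e-10,
                           maxit = 200) {
  ll <- firth_loglik(beta, X, y)
  info <- NULL
  for (it in seq_len(maxit)) {
    st <- firth_step(beta, X, y, free)
    info <- st$info
    if (max(abs(st$score)) < 1e-10) break
    step <- st$delta
    # step-halving on the penalized log-likelihood
    for (half in 0:20) {
      cand <- beta + step / 2^half
      ll_new <- firth_loglik(cand, X, y)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
    }
    if (max(abs(cand - beta)) < tol) { beta <- cand; ll <- ll_new; break }
    beta <- cand; ll <- ll_new
  }
  list(beta = beta, loglik = ll, info = info)
}

# penalized profile log-likelihood: beta_j fixed at `value`, others free
firth_profile <- function(X, y, j, value, start) {
  beta <- start
  beta[j] <- value
  free <- setdiff(seq_len(ncol(X)), j)
  if (length(free) == 0L) return(firth_loglik(beta, X, y))
  firth_maximize(X, y, beta = beta, free = free)$loglik
}

#' Firth-penalized logistic regression
#'
#' Maximizes the Jeffreys-prior penalized likelihood
#' `l(beta) + 0.5 * log det I(beta)` by modified-score iteration with
#' step-halving, which yields finite estimates even under complete
#' separation and reduces small-sample bias. Confidence intervals are
#' profile-penalized-likelihood intervals (inverting the penalized
#' likelihood-ratio test at 95%), falling back to Wald intervals when
#' profiling fails; p-values are penalized likelihood-ratio tests per term.
#'
#' @param x Covariate data frame or matrix (no intercept column).
#' @param y Binary outcome (0/1 or logical).
#' @param ci `"profile"` (default) or `"wald"`.
#' @return Data frame: `term`, `log_odds`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p`, `ci_type`.
#' @export
fit_firth_logistic <- function(x, y, ci = c("profile", "wald")) {
  ci <- match.arg(ci)
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)))
  X <- design_matrix(x)
  if (qr(X)$rank < ncol(X)) stop("singular design matrix")
  fit <- firth_maximize(X, y)
  beta <- fit$beta
  se <- sqrt(diag(solve(fit$info)))
  k <- ncol(X)
  lo <- hi <- pval <- numeric(k)
  ci_type <- rep(ci, k)
  crit <- stats::qchisq(0.95, 1) / 2
  for (j in seq_len(k)) {
    # penalized LRT p-value
    ll0 <- firth_profile(X, y, j, 0, beta)
    pval[j] <- stats::pchisq(2 * (fit$loglik - ll0), df = 1,
                             lower.tail = FALSE)
    if (ci == "wald") {
      lo[j] <- beta[j] - stats::qnorm(0.975) * se[j]
      hi[j] <- beta[j] + stats::qnorm(0.975) * se[j]
      next
    }
    bound <- function(direction) {
      f <- function(v) fit$loglik - firth_profile(X, y, j, v, beta) - crit
      step <- max(se[j], 0.1)
      for (mult in 1:60) {
        v <- beta[j] + direction * mult * step
        if (f(v) > 0) {
          return(stats::uniroot(f, sort(c(beta[j], v)), tol = 1e-6)$root)
        }
      }
      NA_real_
    }
    lo[j] <- bound(-1); hi[j] <- bound(1)
    if (is.na(lo[j]) || is.na(hi[j])) {
      lo[j] <- beta[j] - stats::qnorm(0.975) * se[j]
      hi[j] <- beta[j] + stats::qnorm(0.975) * se[j]
      ci_type[j] <- "wald"
    }
  }
  data.frame(term = colnames(X), log_odds = unname(beta),
             odds_ratio = unname(exp(beta)), ci_low = exp(lo),
             ci_high = exp(hi), p = pval, ci_type = ci_type,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment: `q(i) = min_(j >= i) p(j) * m / j` over the
#' sorted p-values, capped at 1, returned in the original order.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided test of distributional shift. For combined sample sizes up to
#' `exact_max` the p-value is exact, computed by full enumeration of rank
#' assignments with mid-ranks for ties; above that, a normal approximation
#' with tie-corrected variance is used.
#'
#' @param x,y Numeric vectors (non-empty).
#' @param exact_max Largest `length(x) + length(y)` for exact enumeration
#'   (default 12).
#' @return List: `U` (statistic for `x`), `p`.
#' @export
mann_whitney <- function(x, y, exact_max = 12L) {
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("both samples must be non-empty")
  n <- nx + ny
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (n <= exact_max) {
    idx <- utils::combn(n, nx)
    uall <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(uall - mu) >= abs(u - mu) - 1e-9)
  } else {
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = u, p = min(p, 1))
}

#' 2x2 odds ratio with Fisher exact test
#'
#' For the table `[[a, b], [c, d]]` (rows = exposure, columns = outcome):
#' the `"sample"` odds ratio is the cross-product `a*d / (b*c)`, with 0.5
#' added to every cell when any cell is zero; `"fisher_exact"` reports the
#' conditional maximum-likelihood odds ratio. In both cases the p-value is
#' the conditional exact two-sided Fisher p (summing hypergeometric tables
#' with probability at most that of the observed table).
#'
#' @param a,b,c,d Non-negative cell counts.
#' @param method `"sample"` (default) or `"fisher_exact"`.
#' @return List: `or`, `p`.
#' @export
or_2x2 <- function(a, b, c, d, method = c("sample", "fisher_exact")) {
  method <- match.arg(method)
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("counts must be non-negative")
  if (sum(cells) == 0) stop("all-zero table")
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(tab)
  or <- if (method == "sample") {
    if (any(cells == 0)) cells <- cells + 0.5
    (cells[1] * cells[4]) / (cells[2] * cells[3])
  } else {
    unname(ft$estimate)
  }
  list(or = or, p = ft$p.value)
}

#' Encode a three-level amplification class
#'
#' Levels `other_focal` (reference), `ecDNA`, `none`: with
#' "other focal amplification" as the reference, the `ecDNA` coefficient of
#' a Cox model is the ecDNA-versus-chromosomal-amplification contrast.
#'
#' @param has_ecdna Logical: sample carries >= 1 ecDNA.
#' @param has_other_focal Logical: sample carries a non-ecDNA focal
#'   amplification.
#' @return Factor with levels `other_focal`, `ecDNA`, `none`.
#' @export
encode_amplification <- function(has_ecdna, has_other_focal) {
  cls <- ifelse(has_ecdna, "ecDNA",
                ifelse(has_other_focal, "other_focal", "none"))
  factor(cls, levels = c("other_focal", "ecDNA", "none"))
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood maximization with Efron tie handling (via
#' `survival::coxph`) and Wald confidence intervals.
#'
#' @param x Covariate data frame (factors allowed).
#' @param time Positive survival/censoring times.
#' @param event Event indicator (1 = death observed, 0 = censored).
#' @return Data frame: `term`, `hazard_ratio`, `ci_low`, `ci_high`, `p`.
#' @export
fit_cox <- function(x, time, event) {
  event <- as.integer(event)
  if (any(time <= 0)) stop("times must be positive")
  if (sum(event) == 0) stop("no events observed")
  dat <- as.data.frame(x)
  dat$.time <- time
  dat$.event <- event
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", setdiff(names(dat), c(".time", ".event"))),
          collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  s <- summary(fit)
  data.frame(term = rownames(s$coefficients),
             hazard_ratio = unname(s$coefficients[, "exp(coef)"]),
             ci_low = unname(s$conf.int[, "lower .95"]),
             ci_high = unname(s$conf.int[, "upper .95"]),
             p = unname(s$coefficients[, "Pr(>|z|)"]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Encode a feature for association modelling
#'
#' Features observed (non-zero) in fewer than half the samples enter as
#' present/absent; features observed in at least half enter as above/below
#' the median; anything declared continuous is passed through unchanged.
#'
#' @param x Numeric feature vector (e.g. a mutational-signature
#'   attribution).
#' @param continuous Pass through as-is (default FALSE).
#' @return Numeric vector (0/1 encoded unless `continuous`).
#' @export
encode_feature <- function(x, continuous = FALSE) {
  if (continuous) return(x)
  present <- x != 0 & !is.na(x)
  if (mean(present) < 0.5) {
    as.integer(present)
  } else {
    as.integer(x > stats::median(x, na.rm = TRUE))
  }
}

#' Run a family of association models over a cohort table
#'
#' Fits one logistic (or Firth) model per entry of `models`, each with a
#' focus term plus adjustment covariates, and applies BH-FDR across the
#' focus-term p-values of the family.
#'
#' @param cohort Data frame with one row per sample.
#' @param models List of model specs: each a list with `name`, `outcome`
#'   (column name of a binary outcome), `focus` (column name of the term of
#'   interest), `covariates` (character vector of adjustment columns, may be
#'   empty), and optional `family` (`"logistic"` default, or `"firth"`).
#' @return Data frame with one row per focus term: `model`, `term`,
#'   `log_odds`, `odds_ratio`, `ci_low`, `ci_high`, `p`, `q`.
#' @export
run_association_suite <- function(cohort, models) {
  rows <- lapply(models, function(m) {
    cols <- c(m$outcome, m$focus, m$covariates)
    missing_cols <- setdiff(cols, names(cohort))
    if (length(missing_cols)) {
      stop("missing covariate column(s): ", paste(missing_cols,
                                                  collapse = ", "))
    }
    x <- cohort[, c(m$focus, m$covariates), drop = FALSE]
    y <- cohort[[m$outcome]]
    fam <- m$family %||% "logistic"
    fit <- if (fam == "firth") fit_firth_logistic(x, y) else
      fit_logistic(x, y)
    hit <- grep(paste0("^", m$focus), fit$term)
    out <- fit[hit, , drop = FALSE]
    out$model <- m$name %||% m$focus
    out
  })
  out <- do.call(rbind, lapply(rows, function(r)
    r[, c("model", "term", "log_odds", "odds_ratio", "ci_low", "ci_high",
          "p")]))
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
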