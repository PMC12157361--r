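# expand a 2x2 table [[a, b], [c, d]] (exposure rows, outcome columns) into
# subject-level vectors
table_2x2 <- function(a, b, c, d) {
  list(x = c(rep(1, a + b), rep(0, c + d)),
       y = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)))
}

test_that("logistic regression reproduces closed-form 2x2 estimates", {
  t1 <- table_2x2(10, 5, 2, 8)
  fit <- fit_logistic(data.frame(x = t1$x), t1$y)
  expect_equal(fit$odds_ratio[fit$term == "x"], 8, tolerance = 1e-6)
  # balanced independence: OR exactly 1
  t0 <- table_2x2(10, 10, 10, 10)
  fit0 <- fit_logistic(data.frame(x = t0$x), t0$y)
  expect_equal(fit0$odds_ratio[fit0$term == "x"], 1, tolerance = 1e-8)
  # separation is refused with advice
  ts <- table_2x2(10, 0, 0, 10)
  expect_error(fit_logistic(data.frame(x = ts$x), ts$y), "separation")
})

test_that("logistic estimates match a generic optimizer's maximum", {
  set.seed(66)
  for (rep in 1:10) {
    n <- 60
    x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x1 - 0.5 * x2))
    fit <- fit_logistic(data.frame(x1 = x1, x2 = x2), y)
    X <- cbind(1, x1, x2)
    nll <- function(b) -sum(y * (X %*% b) - log1p(exp(X %*% b)))
    opt <- optim(c(0, 0, 0), nll, method = "BFGS",
                 control = list(reltol = 1e-14))
    expect_equal(fit$log_odds, unname(opt$par), tolerance = 1e-5)
  }
})

test_that("Firth fits equal the half-cell correction on 2x2 tables", {
  t1 <- table_2x2(10, 5, 2, 8)
  fit <- fit_firth_logistic(data.frame(x = t1$x), t1$y)
  expect_equal(fit$odds_ratio[fit$term == "x"],
               (10.5 * 8.5) / (5.5 * 2.5), tolerance = 1e-6)
  # completely separated: finite where the MLE diverges
  ts <- table_2x2(10, 0, 0, 10)
  fs <- fit_firth_logistic(data.frame(x = ts$x), ts$y)
  expect_true(all(is.finite(fs$log_odds)))
  expect_lt(fs$p[fs$term == "x"], 0.01)
})

test_that("Firth estimates maximize the penalized likelihood", {
  set.seed(67)
  for (rep in 1:5) {
    n <- 40
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.5 * x))
    fit <- fit_firth_logistic(data.frame(x = x), y, ci = "wald")
    X <- cbind(1, x)
    npl <- function(b) {
      eta <- drop(X %*% b); p <- plogis(eta)
      w <- p * (1 - p)
      -(sum(y * eta - log1p(exp(eta))) +
          0.5 * determinant(crossprod(X * sqrt(w)))$modulus[1])
    }
    opt <- optim(c(0, 0), npl, method = "BFGS",
                 control = list(reltol = 1e-14))
    expect_equal(fit$log_odds, unname(opt$par), tolerance = 1e-4)
  }
})

test_that("the Firth penalty vanishes with growing samples", {
  set.seed(68)
  n <- 10000
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.5 + 0.7 * x))
  mle <- fit_logistic(data.frame(x = x), y)
  firth <- fit_firth_logistic(data.frame(x = x), y, ci = "wald")
  expect_equal(firth$log_odds[2], mle$log_odds[2], tolerance = 0.01)
})

test_that("BH adjustment follows the step-up rule and its invariances", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  set.seed(4)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Mann-Whitney is exact for small samples and symmetric", {
  mw <- mann_whitney(1:3, 4:6)
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)   # 2 / choose(6, 3)
  mw2 <- mann_whitney(4:6, 1:3)
  expect_equal(mw2$p, mw$p)
  # large-sample path agrees with the tie-corrected normal approximation
  set.seed(21)
  x <- rnorm(40); y <- rnorm(45, 0.4)
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  got <- mann_whitney(x, y)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  # ties handled via mid-ranks in the exact path
  expect_silent(mann_whitney(c(1, 1, 2), c(2, 3, 3)))
})

test_that("2x2 odds ratios and Fisher p-values are as defined", {
  res <- or_2x2(31, 84, 4, 56)
  expect_equal(res$or, 1736 / 336, tolerance = 1e-12)
  null <- or_2x2(10, 10, 10, 10)
  expect_equal(null$or, 1)
  expect_equal(null$p, 1)
  # zero cells get the half correction
  z <- or_2x2(5, 0, 3, 7)
  expect_equal(z$or, (5.5 * 7.5) / (0.5 * 3.5))
  expect_error(or_2x2(0, 0, 0, 0), "all-zero")
  # exact p matches hypergeometric enumeration for moderate totals
  set.seed(14)
  for (rep in 1:15) {
    cells <- as.vector(rmultinom(1, sample(10:50, 1), rep(0.25, 4)))
    if (sum(cells) == 0) next
    got <- or_2x2(cells[1], cells[2], cells[3], cells[4])$p
    expect_equal(got, oracle_fisher_p(cells[1], cells[2], cells[3],
                                      cells[4]), tolerance = 1e-7)
  }
})

test_that("Cox fits match brute-force partial-likelihood maximization", {
  # small no-ties dataset, single binary covariate
  set.seed(24)
  x <- rep(0:1, each = 8)
  time <- round(rexp(16, ifelse(x == 1, 0.4, 0.2)), 6)
  event <- rbinom(16, 1, 0.8)
  event[1] <- 1
  fit <- fit_cox(data.frame(x = x), time, event)
  opt <- optimize(function(b) -oracle_cox_loglik(b, x, time, event),
                  c(-5, 5), tol = 1e-9)
  expect_equal(fit$hazard_ratio[1], exp(opt$minimum), tolerance = 1e-4)
  # rank invariance: doubling all times changes nothing
  fit2 <- fit_cox(data.frame(x = x), 2 * time, event)
  expect_equal(fit2$hazard_ratio, fit$hazard_ratio, tolerance = 1e-10)
  expect_error(fit_cox(data.frame(x = x), time, rep(0, 16)), "no events")
})

test_that("null covariates give hazard ratios near one", {
  set.seed(25)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.2)
  event <- as.integer(rexp(n, 0.05) > time)
  fit <- fit_cox(data.frame(x = x), time, event)
  expect_gt(fit$hazard_ratio[1], 0.75)
  expect_lt(fit$hazard_ratio[1], 1.33)
})

test_that("amplification encoding uses other-focal as the reference", {
  f <- encode_amplification(c(TRUE, FALSE, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(levels(f), c("other_focal", "ecDNA", "none"))
  expect_equal(as.character(f), c("ecDNA", "other_focal", "none"))
})

test_that("the association suite is order-invariant and FDR-corrected", {
  set.seed(26)
  co <- simulate_cohort(simulation_config(n_samples = 400, rng_seed = 8))
  cohort <- co$clinical
  cohort$null_feature <- rbinom(nrow(cohort), 1, 0.5)
  models <- list(
    list(name = "wgd", outcome = "has_ecdna", focus = "is_wgd",
         covariates = c("age", "sex")),
    list(name = "null", outcome = "has_ecdna", focus = "null_feature",
         covariates = c("age", "sex")))
  res <- run_association_suite(cohort, models)
  expect_true(all(res$q >= res$p - 1e-12))
  perm <- sample(nrow(cohort))
  res2 <- run_association_suite(cohort[perm, ], models)
  expect_equal(res$odds_ratio, res2$odds_ratio, tolerance = 1e-8)
  expect_error(run_association_suite(cohort,
                                     list(list(outcome = "has_ecdna",
                                               focus = "absent_col",
                                               covariates = character()))),
               "absent_col")
})

test_that("feature encoding switches between presence and median splits", {
  sparse <- c(rep(0, 70), runif(30))
  expect_equal(encode_feature(sparse), as.integer(sparse != 0))
  dense <- runif(100)
  enc <- encode_feature(dense)
  expect_equal(enc, as.integer(dense > median(dense)))
  expect_identical(encode_feature(dense, continuous = TRUE), dense)
})
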