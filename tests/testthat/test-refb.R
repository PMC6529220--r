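test_that("the success probability follows the rectified exponential", {
  expect_equal(refb_probability(refb_params(0.6, 0.9, 0.3), -0.5), 0.6)
  expect_equal(refb_probability(refb_params(0.6, 0.6, 2), c(-1, 0, 0.5, 1)),
               rep(0.6, 4))
  expect_equal(refb_probability(refb_params(0.5, 1, 0.25), 0.25),
               1 - 0.5 * exp(-1))
  # continuity at rho = 0
  expect_equal(refb_probability(refb_params(0.55, 0.95, 0.3), 1e-12),
               0.55, tolerance = 1e-9)
})

test_that("the log-likelihood matches a longhand per-record oracle", {
  set.seed(5)
  for (i in 1:10) {
    d <- simulate_from_refb(refb_params(0.6, 0.9, 0.4), 8, 12, c(-0.3, 0.9),
                            seed = i)
    par <- c(runif(1, 0.3, 0.7), runif(1, 0.6, 0.99), runif(1, 0.05, 2))
    expect_equal(refb_loglik(par, d),
                 oracle_refb_loglik(par[1], par[2], par[3], d),
                 tolerance = 1e-10)
  }
  bad <- tibble::tibble(rho = 0.1, correct = 5L, trials = 3L)
  expect_error(refb_loglik(c(0.5, 0.9, 0.3), bad), "data error")
})

test_that("the null fit is the pooled rate with a matching likelihood", {
  d <- tibble::tibble(rho = c(-0.1, 0.4), correct = c(10L, 15L),
                      trials = c(20L, 20L))
  nf <- fit_null(d)
  expect_equal(unname(nf$params["beta0"]), 25 / 40)
  expect_equal(nf$loglik, refb_loglik(c(25 / 40, 25 / 40, 1), d))
  # all-correct data pushes the pooled rate to the upper clamp
  d2 <- tibble::tibble(rho = c(0.1, 0.5, 0.9), correct = c(10L, 10L, 10L),
                       trials = c(10L, 10L, 10L))
  expect_equal(unname(fit_null(d2)$params["beta0"]), 1 - 1e-4)
  expect_true(fit_null(d2)$boundary)
})

test_that("maximum-likelihood fitting is deterministic and recovers the curve", {
  truth <- refb_params(0.55, 0.95, 0.3)
  d <- simulate_from_refb(truth, 200, 72, c(-0.1, 0.9), seed = 20)
  f1 <- fit_refb(d, n_starts = 20, seed = 2)
  f2 <- fit_refb(d, n_starts = 20, seed = 2)
  expect_identical(unlist(f1$params), unlist(f2$params))
  expect_true(f1$converged)
  grid <- seq(0, 1, by = 0.01)
  sup <- max(abs(refb_probability(f1$params, grid) -
                   refb_probability(truth, grid)))
  expect_lt(sup, 0.02)  # large-N recovery
  # fitted curve is monotone when beta1 >= beta0
  if (f1$params[["beta1"]] >= f1$params[["beta0"]]) {
    expect_true(all(diff(refb_probability(f1$params, grid)) >= -1e-12))
  }
})

test_that("all-nonpositive rho leaves lambda unidentified and is flagged", {
  d <- simulate_from_refb(refb_params(0.7, 0.7, 1), 10, 20, c(-0.9, -0.1),
                          seed = 3)
  f <- fit_refb(d, n_starts = 10, seed = 1)
  expect_true(f$boundary)
})

test_that("the likelihood-ratio test has its trivial fixed points", {
  d <- simulate_from_refb(refb_params(0.7, 0.7, 1), 12, 30, c(-0.2, 0.8),
                          seed = 9)
  nf <- fit_null(d)
  self <- lr_test(nf, nf)
  expect_equal(self$chi2, 0)
  expect_equal(self$p, 1)
  other <- simulate_from_refb(refb_params(0.7, 0.7, 1), 12, 30, c(-0.2, 0.8),
                              seed = 10)
  expect_error(lr_test(fit_refb(d, 5, seed = 1), fit_null(other)),
               "data mismatch")
})

test_that("the model has power against a strong effect", {
  truth <- refb_params(0.55, 0.95, 0.3)
  rejected <- vapply(1:40, function(s) {
    d <- simulate_from_refb(truth, 20, 72, c(-0.1, 0.9), seed = 500 + s)
    lr_test(fit_refb(d, 10, seed = s), fit_null(d))$p < 0.05
  }, logical(1))
  expect_gte(mean(rejected), 0.9)
})

test_that("the profile band brackets the fit and widens with more samples", {
  d <- simulate_from_refb(refb_params(0.55, 0.95, 0.3), 20, 72, c(-0.1, 0.9),
                          seed = 33)
  f <- fit_refb(d, 20, seed = 1)
  b1 <- profile_ci_band(f, n_samples = 2000, seed = 7)
  expect_true(all(b1$lower <= b1$fit + 1e-12 & b1$fit <= b1$upper + 1e-12))
  b2 <- profile_ci_band(f, n_samples = 4000, seed = 7)
  expect_true(all(b2$lower <= b1$lower + 1e-12))
  expect_true(all(b2$upper >= b1$upper - 1e-12))
})

test_that("the band approximates dense-grid profile-likelihood limits", {
  # near-quadratic likelihood at large N: compare the band at rho = 0.5
  # with a brute-force profile over a dense parameter grid
  truth <- refb_params(0.6, 0.9, 0.3)
  d <- simulate_from_refb(truth, 400, 72, c(-0.1, 0.9), seed = 44)
  f <- fit_refb(d, 20, seed = 1)
  b <- profile_ci_band(f, rho_grid = 0.5, n_samples = 2e5, seed = 8)
  g <- as.matrix(expand.grid(
    b0 = seq(max(0.01, f$params[["beta0"]] - 0.12),
             min(0.99, f$params[["beta0"]] + 0.12), length.out = 40),
    b1 = seq(max(0.01, f$params[["beta1"]] - 0.12),
             min(0.99, f$params[["beta1"]] + 0.12), length.out = 40),
    lam = exp(seq(log(f$params[["lambda"]] / 3),
                  log(f$params[["lambda"]] * 3), length.out = 40))
  ))
  ll <- refb_loglik_draws(g, d)
  keep <- g[ll >= f$loglik - qchisq(0.95, 3) / 2, , drop = FALSE]
  pr <- refb_prob_matrix(keep, 0.5)
  expect_equal(b$lower, min(pr), tolerance = 0.015)
  expect_equal(b$upper, max(pr), tolerance = 0.015)
})

test_that("band coverage of the true curve is near nominal at cohort scale", {
  truth <- refb_params(0.55, 0.95, 0.3)
  grid <- seq(0, 0.9, by = 0.05)
  p_true <- refb_probability(truth, grid)
  covered <- vapply(1:100, function(s) {
    d <- simulate_from_refb(truth, 20, 72, c(-0.1, 0.9), seed = 900 + s)
    f <- fit_refb(d, 10, seed = s)
    b <- profile_ci_band(f, rho_grid = grid, n_samples = 2e4, seed = s)
    all(b$lower - 1e-9 <= p_true & p_true <= b$upper + 1e-9)
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("the Laplace Bayes factor matches grid integration on a small dataset", {
  d <- simulate_from_refb(refb_params(0.6, 0.9, 0.3), 15, 40, c(-0.2, 0.9),
                          seed = 55)
  f <- fit_refb(d, 20, seed = 1)
  nf <- fit_null(d)
  lbf <- laplace_log10_bf(f, nf)
  # Brute-force marginal likelihoods over the parameter box (flat measure;
  # the estimator drops constant 2*pi factors, restored here for comparison).
  nb <- 60
  b0s <- seq(0.3, 0.95, length.out = nb)
  b1s <- seq(0.5, 0.999, length.out = nb)
  lams <- exp(seq(log(0.02), log(3), length.out = nb))
  g <- as.matrix(expand.grid(b0 = b0s, b1 = b1s, lam = lams))
  ll <- refb_loglik_draws(g, d)
  w <- exp(ll - max(ll))
  # cell volume on the log-spaced lambda grid: forward differences
  dlam <- c(diff(lams), diff(lams)[nb - 1])
  cellw <- diff(b0s)[1] * diff(b1s)[1] * dlam[match(g[, 3], lams)]
  log_m_full <- max(ll) + log(sum(w * cellw))
  p0 <- seq(0.5, 0.95, length.out = 4000)
  llnull <- vapply(p0, function(p) refb_loglik(c(p, p, 1), d), numeric(1))
  log_m_null <- max(llnull) + log(sum(exp(llnull - max(llnull))) * diff(p0)[1])
  oracle <- (log_m_full - log_m_null) / log(10)
  expect_equal(lbf + log10(2 * pi), oracle, tolerance = 0.2)
  # identical fits give a log BF of zero by construction
  expect_equal(laplace_log10_bf(f, f), 0)
})

test_that("range coverage summarizes the fitted span of the curve", {
  expect_equal(range_coverage(refb_params(0.7, 0.7, 1)), 0)
  expect_equal(range_coverage(refb_params(0.5, 1, 1e-9)), 1, tolerance = 1e-6)
  expect_equal(range_coverage(refb_params(0.5, 1, 1)), 1 - exp(-1))
})

test_that("tidy, glance and autoplot methods work on fits", {
  d <- simulate_from_refb(refb_params(0.55, 0.95, 0.3), 20, 72, c(-0.1, 0.9),
                          seed = 77)
  f <- fit_refb(d, 10, seed = 1)
  td <- generics::tidy(f)
  expect_equal(td$term, c("beta0", "beta1", "lambda"))
  gl <- generics::glance(f)
  expect_equal(gl$n, 20)
  expect_s3_class(ggplot2::autoplot(f, band = profile_ci_band(f,
    n_samples = 1000, seed = 1)), "ggplot")
})
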