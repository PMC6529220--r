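#' Rectified exponential-binomial parameters
#'
#' The model links a participant's familiarity accuracy to their pulling
#' correlation `rho` through a rectified saturating exponential:
#' success probability `P(rho) = beta0` for `rho <= 0` and
#' `P(rho) = beta1 + (beta0 - beta1) * exp(-rho / lambda)` for `rho > 0`,
#' with the number of correct familiarity trials `T_c ~ Binomial(P(rho), T)`.
#' `beta0` is the baseline accuracy of participants with chance or
#' below-chance pulling performance, `beta1` the asymptotic accuracy as
#' `rho` grows, and `lambda` the rate of rise.
#'
#' @param beta0,beta1 Probabilities in \[0, 1\].
#' @param lambda Positive rate constant.
#' @return A named numeric vector of class `refb_params`.
#' @export
refb_params <- function(beta0, beta1, lambda) {
  stopifnot(beta0 >= 0, beta0 <= 1, beta1 >= 0, beta1 <= 1, lambda > 0)
  structure(c(beta0 = beta0, beta1 = beta1, lambda = lambda),
            class = "refb_params")
}

#' Success probability of the rectified exponential-binomial
#'
#' @param params An [refb_params()] (or numeric vector `c(beta0, beta1,
#'   lambda)`).
#' @param rho Pulling correlation(s) in \[-1, 1\].
#' @return Probabilities, continuous at `rho = 0`.
#' @export
refb_probability <- function(params, rho) {
  b0 <- params[[1]]; b1 <- params[[2]]; lam <- params[[3]]
  ifelse(rho <= 0, b0, b1 + (b0 - b1) * exp(-rho / lam))
}

# Clamp probabilities away from {0, 1} before logging.
.refb_eps <- 1e-9

#' Log-likelihood of the rectified exponential-binomial
#'
#' Full binomial log-likelihood, including the binomial coefficient term (so
#' absolute marginal-likelihood comparisons are well defined; it cancels in
#' likelihood ratios).
#'
#' @param params An [refb_params()] or numeric `c(beta0, beta1, lambda)`.
#' @param data A tibble with columns `rho`, `correct`, `trials` (see
#'   [simulate_from_refb()]).
#' @return The scalar log-likelihood.
#' @export
refb_loglik <- function(params, data) {
  if (any(data$correct < 0 | data$correct > data$trials)) {
    stop("data error: counts must satisfy 0 <= correct <= trials.",
         call. = FALSE)
  }
  p <- pmin(pmax(refb_probability(params, data$rho), .refb_eps), 1 - .refb_eps)
  sum(lchoose(data$trials, data$correct) + data$correct * log(p) +
        (data$trials - data$correct) * log(1 - p))
}

#' Fit the rectified exponential-binomial by maximum likelihood
#'
#' Bounded quasi-Newton (`optim(method = "L-BFGS-B")`) from multiple starts: a
#' moment-based start (`beta0` from the pooled rate of participants with
#' `rho <= 0` — falling back to the overall pooled rate when there are none —
#' `beta1` from the pooled rate of the top half of `rho`) plus seeded
#' Latin-hypercube starts over the box `beta in [1e-4, 1 - 1e-4]`,
#' `lambda in [1e-3, 10]`. Ties are broken by highest log-likelihood, then
#' smallest `lambda`. The Hessian of the *negative* log-likelihood at the
#' optimum is computed by central finite differences (step `1e-4`, relative
#' for parameters above 1).
#'
#' @param data A tibble with `rho`, `correct`, `trials`.
#' @param n_starts Number of optimizer starts including the moment start
#'   (default 20).
#' @param seed Seed for the Latin-hypercube starts.
#' @return An object of class `refb_fit`: `params`, `loglik`, `hessian`,
#'   `converged`, `n_starts`, `data`, `boundary` (TRUE when the optimum sits
#'   on the box boundary or `lambda` is unidentified because no `rho` is
#'   positive).
#' @export
fit_refb <- function(data, n_starts = 20, seed = 1) {
  stopifnot(nrow(data) >= 3)
  if (length(unique(data$rho)) < 2) {
    stop("non-degenerate spread of rho is required to fit the model.",
         call. = FALSE)
  }
  lower <- c(1e-4, 1e-4, 1e-3)
  upper <- c(1 - 1e-4, 1 - 1e-4, 10)
  nll <- function(par) -refb_loglik(par, data)
  # Analytic gradient of the negative log-likelihood (clamped points
  # contribute near-zero probability mass and are left to the clamp).
  nll_grad <- function(par) {
    b0 <- par[1]; b1 <- par[2]; lam <- par[3]
    pos <- data$rho > 0
    e <- ifelse(pos, exp(-data$rho / lam), 1)
    p <- pmin(pmax(ifelse(pos, b1 + (b0 - b1) * e, b0), .refb_eps),
              1 - .refb_eps)
    dl_dp <- data$correct / p - (data$trials - data$correct) / (1 - p)
    dp_db0 <- e
    dp_db1 <- ifelse(pos, 1 - e, 0)
    dp_dlam <- ifelse(pos, (b0 - b1) * e * data$rho / lam^2, 0)
    -c(sum(dl_dp * dp_db0), sum(dl_dp * dp_db1), sum(dl_dp * dp_dlam))
  }

  pooled <- sum(data$correct) / sum(data$trials)
  neg <- data$rho <= 0
  b0_start <- if (any(neg)) sum(data$correct[neg]) / sum(data$trials[neg]) else pooled
  top <- data$rho >= stats::median(data$rho)
  b1_start <- sum(data$correct[top]) / sum(data$trials[top])
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  starts <- rbind(c(clamp(b0_start, 0.01, 0.99), clamp(b1_start, 0.01, 0.99), 0.3))
  if (n_starts > 1) {
    rng <- local_rng(seed)
    lh <- rng_eval(rng, function() lhs::randomLHS(n_starts - 1L, 3L))
    starts <- rbind(starts, cbind(
      lower[1] + lh[, 1] * (upper[1] - lower[1]),
      lower[2] + lh[, 2] * (upper[2] - lower[2]),
      exp(log(lower[3]) + lh[, 3] * (log(upper[3]) - log(lower[3])))
    ))
  }
  best <- NULL
  any_ok <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], nll, gr = nll_grad, method = "L-BFGS-B",
            lower = lower, upper = upper, control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    any_ok <- TRUE
    if (is.null(best) || fit$value < best$value - 1e-10 ||
          (abs(fit$value - best$value) <= 1e-10 && fit$par[3] < best$par[3])) {
      best <- fit
    }
  }
  if (!any_ok) {
    stop("non-convergence: all optimizer starts failed (",
         nrow(starts), " starts tried).", call. = FALSE)
  }
  par <- best$par
  names(par) <- c("beta0", "beta1", "lambda")
  hess <- fd_hessian(nll, par)
  on_boundary <- any(par <= lower + 1e-8) || any(par >= upper - 1e-8)
  structure(list(
    params = refb_params(par[["beta0"]], par[["beta1"]], par[["lambda"]]),
    loglik = -best$value,
    hessian = hess,
    converged = best$convergence == 0,
    n_starts = nrow(starts),
    boundary = on_boundary || !any(data$rho > 0),
    df = 3L,
    data = data
  ), class = "refb_fit")
}

# Central finite-difference Hessian of f at x (negative log-likelihood
# curvature). Step 1e-4, relative for coordinates above 1 in magnitude.
fd_hessian <- function(f, x, step = 1e-4) {
  k <- length(x)
  h <- step * pmax(1, abs(x))
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        xp <- x; xm <- x
        xp[i] <- x[i] + h[i]; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpm <- x; xmp <- x; xmm <- x
        xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
        xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
        xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  dimnames(H) <- list(names(x), names(x))
  H
}

#' Fit the constant-probability null model
#'
#' Under the null of no relation between familiarity accuracy and pulling
#' correlation (`beta1 = beta0`, `lambda` without effect) the maximum
#' likelihood is the pooled success rate, available in closed form.
#'
#' @param data A tibble with `rho`, `correct`, `trials`.
#' @return An object of class `refb_fit` with a single parameter `beta0`,
#'   its log-likelihood and the scalar curvature (1 x 1 Hessian of the
#'   negative log-likelihood).
#' @export
fit_null <- function(data) {
  p_hat <- sum(data$correct) / sum(data$trials)
  p_hat <- min(max(p_hat, 1e-4), 1 - 1e-4)
  ll <- refb_loglik(c(p_hat, p_hat, 1), data)
  # d^2(-ll)/dp^2 for the pooled binomial likelihood.
  curv <- sum(data$correct) / p_hat^2 +
    sum(data$trials - data$correct) / (1 - p_hat)^2
  structure(list(
    params = c(beta0 = p_hat),
    loglik = ll,
    hessian = matrix(curv, 1, 1, dimnames = list("beta0", "beta0")),
    converged = TRUE,
    n_starts = 0L,
    boundary = p_hat <= 1e-4 || p_hat >= 1 - 1e-4,
    df = 1L,
    data = data
  ), class = "refb_fit")
}

#' Likelihood-ratio test of the rectified exponential-binomial
#'
#' Compares the full three-parameter fit against the constant-probability null
#' on the same data: `chi2 = 2 * (loglik_full - loglik_null)` (clipped at 0)
#' referred to a chi-square distribution with 2 degrees of freedom.
#'
#' @param full An `refb_fit` from [fit_refb()].
#' @param null An `refb_fit` from [fit_null()].
#' @return A tibble with `chi2`, `df`, `p`.
#' @export
lr_test <- function(full, null) {
  if (!isTRUE(all.equal(full$data, null$data))) {
    stop("data mismatch: the two fits were not computed on the same data.",
         call. = FALSE)
  }
  chi2 <- max(0, 2 * (full$loglik - null$loglik))
  tibble::tibble(chi2 = chi2, df = 2L, p = pchisq(chi2, df = 2,
                                                  lower.tail = FALSE))
}

#' Profile-likelihood confidence band for the fitted curve
#'
#' Samples parameter sets from the Laplace approximation at the maximum
#' likelihood point (Gaussian with covariance the inverse Hessian of the
#' negative log-likelihood), keeps those whose log-likelihood lies within
#' `q/2` of the maximum, where `q` is the `1 - alpha` quantile of the
#' chi-square distribution with `df` degrees of freedom (default 3, the
#' number of estimated parameters), and takes the pointwise extrema of the
#' predicted curves over the retained samples. The maximum-likelihood sample
#' itself is always retained, so the band contains the fitted curve.
#'
#' @param fit An `refb_fit` from [fit_refb()].
#' @param rho_grid Grid of `rho` values for the band.
#' @param alpha Band level (default 0.05 for a 95% band).
#' @param df Chi-square degrees of freedom for the cutoff (default 3).
#' @param n_samples Number of Laplace samples (default 100000).
#' @param seed Integer seed.
#' @return An object of class `refb_band`: a tibble with `rho`, `fit`,
#'   `lower`, `upper`, plus attributes `n_retained` and `alpha`.
#' @export
profile_ci_band <- function(fit, rho_grid = seq(-0.2, 1, by = 0.01),
                            alpha = 0.05, df = 3, n_samples = 1e5, seed = 1) {
  H <- fit$hessian
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    # Fall back to a diagonally regularized curvature (logged via warning).
    warning("Hessian not positive definite; regularizing the diagonal.")
    H <- H + diag(abs(min(ev)) + 1e-6, nrow(H))
  }
  cov <- solve(H)
  L <- chol(cov)
  rng <- local_rng(seed)
  # Row-major fill: the first k draws are shared by any larger n_samples from
  # the same seed, so the band is pointwise monotone in the sample count.
  z <- matrix(rng_rnorm(rng, n_samples * 3L), ncol = 3L, byrow = TRUE)
  draws <- sweep(z %*% L, 2, unlist(fit$params), "+")
  ok <- draws[, 3] > 0 & draws[, 1] >= 0 & draws[, 1] <= 1 &
    draws[, 2] >= 0 & draws[, 2] <= 1
  draws <- draws[ok, , drop = FALSE]
  q <- qchisq(1 - alpha, df)
  ll <- refb_loglik_draws(draws, fit$data)
  keep <- draws[ll >= fit$loglik - q / 2, , drop = FALSE]
  keep <- rbind(unlist(fit$params), keep)  # ML point always qualifies
  if (nrow(keep) == 1 && n_samples > 0 && sum(ok) == 0) {
    stop("degenerate band: no Laplace sample was retained.", call. = FALSE)
  }
  curves <- refb_prob_matrix(keep, rho_grid)   # n_keep x n_grid
  fit_curve <- refb_probability(fit$params, rho_grid)
  band <- tibble::tibble(
    rho = rho_grid,
    fit = fit_curve,
    lower = pmax(0, apply(curves, 2, min)),
    upper = pmin(1, apply(curves, 2, max))
  )
  structure(band, class = c("refb_band", class(band)),
            n_retained = nrow(keep) - 1L, alpha = alpha, df = df,
            n_samples = n_samples, seed = seed)
}

#' Laplace-approximation Bayes factor for the model against the null
#'
#' Approximates each model's marginal likelihood by the likelihood at the
#' maximum-likelihood parameters with the standard Laplace curvature
#' correction (`loglik - log det(H) / 2`, `H` the Hessian of the negative
#' log-likelihood; constant `2*pi` factors ignored as they cancel or do not
#' scale with the data), and returns the base-10 logarithm of the ratio.
#'
#' @param full An `refb_fit` from [fit_refb()].
#' @param null An `refb_fit` from [fit_null()].
#' @return The log10 Bayes factor favouring the full model.
#' @export
laplace_log10_bf <- function(full, null) {
  lap <- function(fit) {
    ld <- determinant(fit$hessian, logarithm = TRUE)
    if (ld$sign <= 0) {
      stop("numerical-curvature error: Hessian determinant not positive.",
           call. = FALSE)
    }
    fit$loglik - 0.5 * as.numeric(ld$modulus)
  }
  (lap(full) - lap(null)) / log(10)
}

#' Range coverage of the fitted curve
#'
#' The share of the attainable familiarity range (fraction correct 0.5 to
#' 1.0) traversed as pulling performance goes from chance (`rho = 0`) to
#' perfect (`rho = 1`): `(P(1) - P(0)) / 0.5`.
#'
#' @param params An [refb_params()].
#' @return A fraction (1 = the curve spans the whole attainable range).
#' @export
range_coverage <- function(params) {
  (refb_probability(params, 1) - refb_probability(params, 0)) / 0.5
}

# Success-probability matrix for many parameter draws (m x 3) over a rho
# grid, and the corresponding vector of log-likelihoods; both fully
# vectorized for the Laplace-sample screening in profile_ci_band().
refb_prob_matrix <- function(draws, rho) {
  b0 <- draws[, 1]; b1 <- draws[, 2]; lam <- draws[, 3]
  pos <- rho > 0
  P <- matrix(b0, nrow = nrow(draws), ncol = length(rho))
  if (any(pos)) {
    E <- exp(-outer(1 / lam, rho[pos]))
    P[, pos] <- b1 + (b0 - b1) * E
  }
  P
}

refb_loglik_draws <- function(draws, data) {
  P <- refb_prob_matrix(draws, data$rho)
  P <- pmin(pmax(P, .refb_eps), 1 - .refb_eps)
  const <- sum(lchoose(data$trials, data$correct))
  as.numeric(log(P) %*% data$correct +
               log1p(-P) %*% (data$trials - data$correct)) + const
}

# --- methods --------------------------------------------------------------

#' @export
print.refb_fit <- function(x, ...) {
  cat(sprintf("<refb_fit> %s\n",
              if (x$df == 1L) "constant-probability null" else "rectified exponential-binomial"))
  print(round(unlist(x$params), 4))
  cat(sprintf("loglik %.3f | converged %s | boundary %s\n",
              x$loglik, x$converged, x$boundary))
  invisible(x)
}

#' Tidy a rectified exponential-binomial fit
#'
#' @param x An `refb_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` and (when the curvature allows)
#'   `std_error` from the inverse Hessian.
#' @method tidy refb_fit
#' @export
tidy.refb_fit <- function(x, ...) {
  se <- tryCatch(sqrt(diag(solve(x$hessian))), error = function(e)
    rep(NA_real_, length(x$params)))
  tibble::tibble(term = names(unlist(x$params)),
                 estimate = as.numeric(unlist(x$params)),
                 std_error = unname(se))
}

#' Glance at a rectified exponential-binomial fit
#'
#' @param x An `refb_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `loglik`, `df`, `n`, `converged`,
#'   `boundary`, `range_coverage` (NA for the null fit).
#' @method glance refb_fit
#' @export
glance.refb_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik, df = x$df, n = nrow(x$data),
    converged = x$converged, boundary = x$boundary,
    range_coverage = if (x$df == 3L) range_coverage(x$params) else NA_real_
  )
}

#' Plot a fitted rectified exponential-binomial
#'
#' Draws the per-participant data (pulling correlation vs familiarity
#' fraction correct) with the fitted curve, and the confidence band when one
#' is supplied.
#'
#' @param object An `refb_fit`.
#' @param band Optionally an `refb_band` from [profile_ci_band()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot refb_fit
#' @export
autoplot.refb_fit <- function(object, band = NULL, ...) {
  d <- object$data
  d$f_c <- d$correct / d$trials
  grid <- tibble::tibble(rho = seq(min(-0.2, min(d$rho)), 1, by = 0.01))
  grid$fit <- refb_probability(object$params, grid$rho)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rho, y = .data$f_c))
  if (!is.null(band)) {
    p <- p + ggplot2::geom_ribbon(
      data = tibble::as_tibble(band),
      ggplot2::aes(x = .data$rho, ymin = .data$lower, ymax = .data$upper),
      inherit.aes = FALSE, fill = "red", alpha = 0.2
    )
  }
  p +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "red", linewidth = 1) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "haptic pulling performance (rho)",
                  y = "visual familiarity performance (fraction correct)") +
    ggplot2::coord_cartesian(ylim = c(0.3, 1)) +
    ggplot2::theme_minimal()
}
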