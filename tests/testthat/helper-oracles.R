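# Independent oracles used across the suite. These deliberately share no code
# with the package internals: fixed-grid quadrature instead of adaptive
# integrate(), longhand per-trial products instead of vectorized binomials,
# closed-form case counts instead of the constraint enumerator.

# Dense fixed-grid Simpson quadrature of f on [a, b] (n odd number of nodes).
simpson <- function(f, a, b, n = 40001L) {
  stopifnot(n %% 2L == 1L)
  x <- seq(a, b, length.out = n)
  w <- c(1, rep(c(4, 2), (n - 3) / 2), 4, 1)
  sum(w * f(x)) * (x[2] - x[1]) / 3
}

# JZS one/two-sample BF10 by Simpson quadrature over g = exp(x).
oracle_jzs_t <- function(t, n_eff, nu, r = sqrt(2) / 2) {
  log_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  f <- function(x) {
    g <- exp(x)
    exp(-0.5 * log1p(n_eff * g) -
          (nu + 1) / 2 * log1p(t^2 / (nu * (1 + n_eff * g))) +
          log(r) - 0.5 * log(2 * pi) - 1.5 * log(g) - r^2 / (2 * g) -
          log_null + x)            # + x: Jacobian of g = exp(x)
  }
  simpson(f, -30, 30)
}

# JZS regression BF10 (mixture-of-g with inverse-gamma(1/2, n/2) on g).
oracle_jzs_regression <- function(r2, n, p) {
  f <- function(x) {
    g <- exp(x)
    exp((n - 1 - p) / 2 * log1p(g) - (n - 1) / 2 * log1p(g * (1 - r2)) +
          0.5 * log(n / 2) - lgamma(0.5) - 1.5 * log(g) - n / (2 * g) + x)
  }
  simpson(f, -30, 30)
}

# Longhand rectified exponential-binomial log-likelihood: per-participant
# binomial density evaluated one record at a time via dbinom.
oracle_refb_loglik <- function(beta0, beta1, lambda, data) {
  ll <- 0
  for (i in seq_len(nrow(data))) {
    rho <- data$rho[i]
    p <- if (rho <= 0) beta0 else beta1 + (beta0 - beta1) * exp(-rho / lambda)
    p <- min(max(p, 1e-9), 1 - 1e-9)
    ll <- ll + log(dbinom(data$correct[i], data$trials[i], p))
  }
  ll
}

# The constructive case formulas for the exposure-scene families.
oracle_scene_counts <- function() {
  n3h <- 3 * 2 * 1 * (1 + 2 * 3)              # identities x geometries
  n2h1v_aligned <- 3 * 2 * 3 * 2 * (1 + 2)
  n2h1v_offset <- 3 * 2 * 2 * 3 * 2
  list(`3H` = n3h, `2H1V_aligned` = n2h1v_aligned, `2H1V_offset` = n2h1v_offset,
       family_total = n3h + n2h1v_aligned + n2h1v_offset,
       grand_total = 2 * (n3h + n2h1v_aligned + n2h1v_offset))
}

# Small deterministic trial log for hand-checked scene scoring: 4 unique
# two-true-pair scenes pulled twice per direction, plus a familiarity phase
# with fixed choices.
toy_consistency_log <- function(forces_hard, forces_easy, choose_pair) {
  inv <- build_inventory(2, 2, seed = 5)
  pt <- generate_pulling_test_design("haptic_exposure", inv, seed = 2)
  pt <- pt[pt$kind_a == "true" & pt$kind_b == "true", ]
  pt$parallel <- (pt$orientation == "h") == (pt$direction == "horizontal")
  pt <- pt[order(pt$scene_code, !pt$parallel), ]
  scene_idx <- match(pt$scene_code, unique(pt$scene_code))
  pt$pull_force_N <- ifelse(pt$parallel, forces_hard[scene_idx],
                            forces_easy[scene_idx])
  fam <- generate_familiarity_design(inv, n_blocks = 2, seed = 3)
  fam$choice <- ifelse(choose_pair(fam$first_pair), "first",
                       ifelse(choose_pair(fam$second_pair), "second",
                              "first"))
  fam$correct <- fam$choice == fam$correct_position
  log <- dplyr::bind_rows(pt[, !(names(pt) %in% "parallel")], fam)
  log$participant_id <- 1L
  list(trials = log, inventory = inv)
}

toy_inventory_true_ids <- function() {
  inv <- build_inventory(2, 2, seed = 5)
  inv$pairs$pair_id[inv$pairs$kind == "true"]
}
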