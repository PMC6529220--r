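#' Per-scene haptic and familiarity scores
#'
#' For every unique ordered two-true-pair scene of the haptic pulling test
#' (12 in the visual-exposure design, 4 in the haptic-exposure design) and
#' every participant, computes a haptic score — the mean pulling force in the
#' direction that breaks the two pairs minus the mean force in the direction
#' that merely separates them, averaged over repetitions — and a familiarity
#' score — the mean, over the scene's two pairs, of the fraction of
#' familiarity trials in which the participant chose that pair.
#'
#' @param trials A trial-log tibble containing `haptic_pulling_test` and
#'   `familiarity_test` rows.
#' @return A tibble with one row per participant x scene: `participant_id`,
#'   `scene_code`, `pair_a`, `pair_b`, `haptic_score`, `familiarity_score`,
#'   `n_reps` (pulling-test rows contributing).
#' @export
scene_scores <- function(trials) {
  need <- c("haptic_pulling_test", "familiarity_test")
  if (!all(need %in% trials$phase)) {
    stop("incomplete log: pulling-test and familiarity-test rows required.",
         call. = FALSE)
  }
  pull <- trials |>
    dplyr::filter(.data$phase == "haptic_pulling_test",
                  .data$kind_a == "true", .data$kind_b == "true") |>
    dplyr::mutate(parallel = (.data$orientation == "h") ==
                    (.data$direction == "horizontal"))
  haptic <- pull |>
    dplyr::group_by(.data$participant_id, .data$scene_code,
                    .data$pair_a, .data$pair_b) |>
    dplyr::summarise(
      haptic_score = mean(.data$pull_force_N[.data$parallel]) -
        mean(.data$pull_force_N[!.data$parallel]),
      n_reps = dplyr::n(), .groups = "drop"
    )
  fam <- trials |>
    dplyr::filter(.data$phase == "familiarity_test") |>
    tidyr::pivot_longer(c("first_pair", "second_pair"),
                        names_to = "slot", values_to = "pair_id") |>
    dplyr::mutate(chosen = (.data$slot == "first_pair") ==
                    (.data$choice == "first")) |>
    dplyr::group_by(.data$participant_id, .data$pair_id) |>
    dplyr::summarise(choice_fraction = mean(.data$chosen), .groups = "drop")
  look <- function(pid, pair) {
    fam$choice_fraction[match(paste(pid, pair),
                              paste(fam$participant_id, fam$pair_id))]
  }
  haptic |>
    dplyr::mutate(
      familiarity_score = (look(.data$participant_id, .data$pair_a) +
                             look(.data$participant_id, .data$pair_b)) / 2
    ) |>
    dplyr::select("participant_id", "scene_code", "pair_a", "pair_b",
                  "haptic_score", "familiarity_score", "n_reps")
}

#' Within-participant object-consistency correlation
#'
#' Pearson correlation, across a participant's unique two-true-pair scenes,
#' between the haptic and familiarity scene scores. When either score has
#' zero variance (e.g. a participant at familiarity ceiling chose every pair
#' always) the correlation is undefined and the participant is flagged, not
#' zeroed.
#'
#' @param scores A [scene_scores()] tibble (one or more participants).
#' @return A tibble with one row per participant: `participant_id`,
#'   `n_scenes`, `consistency`, `defined`.
#' @export
object_consistency <- function(scores) {
  one <- function(df) {
    defined <- nrow(df) >= 3 && sd(df$haptic_score) > 0 &&
      sd(df$familiarity_score) > 0
    tibble::tibble(
      n_scenes = nrow(df),
      consistency = if (defined) cor(df$haptic_score, df$familiarity_score)
        else NA_real_,
      defined = defined
    )
  }
  scores |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}

#' Group test of object consistency
#'
#' One-sample t-test of the per-participant consistency correlations against
#' zero (participants with undefined correlations are dropped; pooling across
#' experiments only changes the degrees of freedom, never an individual's
#' value), with the matching JZS Bayes factor.
#'
#' @param consistency Vector of per-participant consistency correlations
#'   (NAs allowed, dropped).
#' @param scale_r Cauchy prior scale for the Bayes factor.
#' @return A tibble with `mean`, `sem`, `t`, `df`, `p`, `bf10`, `n`.
#' @export
consistency_group_test <- function(consistency, scale_r = sqrt(2) / 2) {
  x <- consistency[!is.na(consistency)]
  if (length(x) < 2) stop("insufficient data: need >= 2 defined correlations.",
                          call. = FALSE)
  if (sd(x) == 0) {
    t_stat <- if (mean(x) == 0) 0 else Inf * sign(mean(x))
    p <- if (t_stat == 0) 1 else 0
    bf <- if (is.finite(t_stat)) jzs_bf_one_sample(t_stat, length(x),
                                                   scale_r)$bf10 else Inf
    return(tibble::tibble(mean = mean(x), sem = 0, t = t_stat,
                          df = length(x) - 1, p = p, bf10 = bf, n = length(x)))
  }
  tt <- t.test(x)
  bf <- jzs_bf_one_sample(unname(tt$statistic), length(x), scale_r)
  tibble::tibble(mean = mean(x), sem = sd(x) / sqrt(length(x)),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, bf10 = bf$bf10, n = length(x))
}

#' Explicitness score from a debriefing record
#'
#' The proportion of true pairs a participant correctly identified at
#' debriefing; incorrect identifications are ignored, and participants who
#' did not notice any pairs score 0.
#'
#' @param noticed Did the participant report noticing pairs?
#' @param n_correct_pairs Number of correctly identified true pairs.
#' @param n_true_pairs Number of true pairs in the inventory.
#' @return Scores in `{0, 1/n, ..., 1}` (vectorized).
#' @export
explicitness_score <- function(noticed, n_correct_pairs, n_true_pairs) {
  if (any(n_correct_pairs > n_true_pairs | n_correct_pairs < 0)) {
    stop("record error: 0 <= n_correct_pairs <= n_true_pairs required.",
         call. = FALSE)
  }
  ifelse(noticed, n_correct_pairs / n_true_pairs, 0)
}

# Indicator-adjusted correlation between y and x allowing experiment-specific
# intercepts but a common slope: the partial correlation of x given the
# experiment indicator, signed by the slope.
indicator_adjusted_r <- function(y, x, experiment) {
  fit <- lm(y ~ x + factor(experiment))
  sm <- summary(fit)
  tval <- sm$coefficients["x", "t value"]
  df <- fit$df.residual
  r <- sign(tval) * sqrt(tval^2 / (tval^2 + df))
  list(r = r, p = sm$coefficients["x", "Pr(>|t|)"],
       r2_full = sm$r.squared,
       r2_indicator = summary(lm(y ~ factor(experiment)))$r.squared)
}

#' Explicitness-controlled partial-correlation analysis
#'
#' Quantifies how much of the across-participant relation between visual
#' familiarity performance and haptic pulling performance survives when
#' explicit knowledge of the pairs is controlled for. The raw relation
#' (`r_full`) is the indicator-adjusted correlation from a regression of
#' visual performance on haptic performance plus an experiment indicator
#' (experiment-specific intercepts, common slope). For the partial relation
#' (`r_partial`), both performances are first residualized on explicitness
#' *within each experiment*, and the same indicator-adjusted regression is
#' run on the residuals. The ratio of explained variances
#' `r_partial^2 / r_full^2` measures the share of the generalisation effect
#' attributable to implicit transfer. JZS regression Bayes factors for adding
#' the haptic covariate to the indicator-only model are attached.
#'
#' @param data A tibble with one row per participant: `visual` (fraction
#'   correct), `haptic` (pulling correlation), `explicitness`, `experiment`.
#' @return A one-row tibble: `r_full`, `p_full`, `bf_full`, `r_partial`,
#'   `p_partial`, `bf_partial`, `variance_ratio`, `n`.
#' @export
explicitness_partial_analysis <- function(data) {
  stopifnot(all(c("visual", "haptic", "explicitness", "experiment") %in%
                  names(data)))
  data <- data[stats::complete.cases(data[, c("visual", "haptic",
                                              "explicitness", "experiment")]), ]
  n <- nrow(data)
  if (n < 4) stop("insufficient data: need >= 4 participants.", call. = FALSE)
  single <- length(unique(data$experiment)) < 2
  if (single) {
    warning("single-experiment input: falling back to plain correlations.")
    data$experiment <- "only"
  }
  adj <- function(y, x) {
    if (single) {
      ct <- cor.test(x, y)
      list(r = unname(ct$estimate), p = ct$p.value,
           r2_full = summary(lm(y ~ x))$r.squared, r2_indicator = 0)
    } else {
      indicator_adjusted_r(y, x, data$experiment)
    }
  }
  full <- adj(data$visual, data$haptic)
  resid_within <- function(y) {
    unsplit(lapply(split(seq_len(n), data$experiment), function(i) {
      if (sd(data$explicitness[i]) == 0) {
        y[i] - mean(y[i])
      } else {
        resid(lm(y[i] ~ data$explicitness[i]))
      }
    }), data$experiment)
  }
  rv <- resid_within(data$visual)
  rh <- resid_within(data$haptic)
  part <- adj(rv, rh)
  inc_bf <- function(a) {
    bf_full <- jzs_regression_bf(a$r2_full, n, if (single) 1 else 2)$bf10
    if (single || a$r2_indicator <= 0) return(bf_full)
    bf_full / jzs_regression_bf(a$r2_indicator, n, 1)$bf10
  }
  tibble::tibble(
    r_full = full$r, p_full = full$p, bf_full = inc_bf(full),
    r_partial = part$r, p_partial = part$p, bf_partial = inc_bf(part),
    variance_ratio = part$r^2 / full$r^2, n = n
  )
}
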