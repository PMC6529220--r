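#' Fraction of correct familiarity choices
#'
#' @param correct Logical (or 0/1) vector of per-trial outcomes, `TRUE` when
#'   the true pair was chosen.
#' @return A tibble with `f_c`, `t_c`, `t_total`.
#' @export
fraction_correct <- function(correct) {
  if (length(correct) < 1) stop("empty input: no familiarity trials.",
                                call. = FALSE)
  stopifnot(!anyNA(correct))
  tibble::tibble(f_c = mean(correct), t_c = as.integer(sum(correct)),
                 t_total = length(correct))
}

#' Pulling correlation
#'
#' Pearson correlation between generated pulling forces and required breakage
#' forces across trials. Zero variance in either series makes the correlation
#' undefined; such cases are flagged (`defined = FALSE`, `rho = NA`), never
#' silently zeroed.
#'
#' @param forces Pulling forces (newtons, already clipped at the force cap).
#' @param breakage Required breakage forces (newtons).
#' @param method `"pearson"` (default, the measure with the t-equivalence
#'   property) or `"spearman"`.
#' @return A tibble with `rho`, `defined`, `n`.
#' @export
pulling_correlation <- function(forces, breakage,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(forces) == length(breakage), length(forces) >= 3,
            !anyNA(forces), !anyNA(breakage))
  if (sd(forces) == 0 || sd(breakage) == 0) {
    return(tibble::tibble(rho = NA_real_, defined = FALSE,
                          n = length(forces)))
  }
  tibble::tibble(rho = cor(forces, breakage, method = method),
                 defined = TRUE, n = length(forces))
}

#' Equivalence of the pulling correlation and the two-level t statistic
#'
#' With exactly two breakage-force levels and equal trial counts per level,
#' the two-sample t statistic comparing mean force between levels and the
#' Pearson correlation carry the same information:
#' `t^2 = rho^2 * (n - 2) / (1 - rho^2)`.
#' The function computes both and returns them together with the identity's
#' two sides (which agree to numerical precision).
#'
#' @param forces Pulling forces.
#' @param breakage Breakage forces taking exactly two values with equal
#'   counts.
#' @return A tibble with `t_stat`, `rho`, `n`, `t_sq`, `t_sq_from_rho`.
#' @export
rho_t_equivalence <- function(forces, breakage) {
  lv <- sort(unique(breakage))
  if (length(lv) != 2) stop("breakage must take exactly two levels.",
                            call. = FALSE)
  n1 <- sum(breakage == lv[1]); n2 <- sum(breakage == lv[2])
  if (n1 != n2) stop("precondition: equal trial counts per level.",
                     call. = FALSE)
  n <- n1 + n2
  tt <- t.test(forces[breakage == lv[2]], forces[breakage == lv[1]],
               var.equal = TRUE)
  rho <- cor(forces, breakage)
  tibble::tibble(t_stat = unname(tt$statistic), rho = rho, n = n,
                 t_sq = unname(tt$statistic)^2,
                 t_sq_from_rho = rho^2 * (n - 2) / (1 - rho^2))
}

#' Paired test for a block trend in test performance
#'
#' Tests for a change in performance between the first and second block of a
#' generalisation test (paired t-test of block 2 minus block 1 across
#' participants) and attaches the matching JZS Bayes factor.
#'
#' @param block1,block2 Per-participant performance in each block (equal
#'   lengths, paired by position).
#' @param scale_r Cauchy prior scale for the Bayes factor.
#' @return A tibble with `mean_diff`, `t`, `df`, `p`, `bf10`.
#' @export
block_trend_test <- function(block1, block2, scale_r = sqrt(2) / 2) {
  ok <- stats::complete.cases(block1, block2)
  if (sum(ok) < 2) stop("insufficient data: need >= 2 complete pairs.",
                        call. = FALSE)
  d <- block2[ok] - block1[ok]
  if (sd(d) == 0) {
    # No spread in the differences: t is 0 (no trend) when all diffs are 0.
    if (all(d == 0)) {
      return(tibble::tibble(mean_diff = 0, t = 0, df = length(d) - 1, p = 1,
                            bf10 = jzs_bf_one_sample(0, length(d),
                                                     scale_r)$bf10))
    }
    stop("degenerate differences: identical nonzero shift in every pair.",
         call. = FALSE)
  }
  tt <- t.test(d)
  bf <- jzs_bf_one_sample(unname(tt$statistic), length(d), scale_r)
  tibble::tibble(mean_diff = mean(d), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value, bf10 = bf$bf10)
}

#' Training-based inclusion rule
#'
#' A participant is included only if their clamp-catch training trials show a
#' significant positive Pearson correlation between pulling force and required
#' breakage force (r > 0 and two-sided p < 0.05). Zero-variance force series
#' make the correlation undefined and the participant is excluded with reason
#' `"undefined correlation"`.
#'
#' @param forces,breakage Clamp-catch training forces and breakage forces.
#' @param alpha Significance level (default 0.05).
#' @return A tibble with `excluded`, `reason`, `r`, `p`.
#' @export
apply_exclusion <- function(forces, breakage, alpha = 0.05) {
  if (length(forces) < 3 || sd(forces) == 0 || sd(breakage) == 0) {
    return(tibble::tibble(excluded = TRUE, reason = "undefined correlation",
                          r = NA_real_, p = NA_real_))
  }
  ct <- cor.test(forces, breakage)
  ok <- unname(ct$estimate) > 0 && ct$p.value < alpha
  tibble::tibble(
    excluded = !ok,
    reason = if (ok) NA_character_ else "no significant positive training correlation",
    r = unname(ct$estimate), p = ct$p.value
  )
}

#' Per-participant performance summary of a trial log
#'
#' Computes the standard summary measures for every participant in a trial
#' log: familiarity fraction correct (overall and per block), pulling
#' correlation between force and breakage force on pulling-test trials
#' (overall and per block), the fraction of force-cap-clipped pulls, and the
#' training-based exclusion flag (evaluated on clamp-catch training trials
#' where present; participants without clamp-catch training are never
#' excluded, mirroring the haptic-exposure experiment's criteria).
#'
#' @param trials A trial-log tibble (see [simulate_experiment()] /
#'   [read_trial_log()]).
#' @param config A [bond_config()] (for the force cap).
#' @return A tibble with one row per participant: `participant_id`,
#'   `experiment`, `f_c`, `t_c`, `t_total`, `rho`, `rho_defined`,
#'   `f_c_block1`, `f_c_block2`, `rho_block1`, `rho_block2`,
#'   `clipped_fraction`, `excluded`, `exclusion_reason`.
#' @export
participant_performance <- function(trials, config = bond_config()) {
  one <- function(df) {
    fam <- if ("correct" %in% names(df)) df[df$phase == "familiarity_test", ]
      else tibble::tibble(correct = logical(), block = integer())
    pull <- df[df$phase == "haptic_pulling_test", ]
    fc <- if (nrow(fam)) fraction_correct(fam$correct) else
      tibble::tibble(f_c = NA_real_, t_c = NA_integer_, t_total = 0L)
    rho_res <- if (nrow(pull) >= 3) {
      pulling_correlation(pull$pull_force_N, pull$breakage_force_N)
    } else tibble::tibble(rho = NA_real_, defined = FALSE, n = nrow(pull))
    block_fc <- function(b) {
      x <- fam$correct[fam$block == b]
      if (length(x)) mean(x) else NA_real_
    }
    block_rho <- function(b) {
      x <- pull[pull$block == b, ]
      if (nrow(x) >= 3 && sd(x$pull_force_N) > 0 &&
            sd(x$breakage_force_N) > 0) {
        cor(x$pull_force_N, x$breakage_force_N)
      } else NA_real_
    }
    cc <- if ("mode" %in% names(df)) {
      df[df$phase == "haptic_training" & df$mode == "clamp_catch", ]
    } else df[0, ]
    excl <- if (nrow(cc)) apply_exclusion(cc$pull_force_N, cc$breakage_force_N)
      else tibble::tibble(excluded = FALSE, reason = NA_character_,
                          r = NA_real_, p = NA_real_)
    tibble::tibble(
      f_c = fc$f_c, t_c = fc$t_c, t_total = fc$t_total,
      rho = rho_res$rho, rho_defined = rho_res$defined,
      f_c_block1 = block_fc(1L), f_c_block2 = block_fc(2L),
      rho_block1 = block_rho(1L), rho_block2 = block_rho(2L),
      clipped_fraction = if (nrow(pull)) {
        mean(pull$pull_force_N >= config$force_cap)
      } else NA_real_,
      excluded = excl$excluded, exclusion_reason = excl$reason
    )
  }
  if (!"experiment" %in% names(trials)) trials$experiment <- NA_character_
  trials |>
    dplyr::group_by(.data$participant_id, .data$experiment) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}
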