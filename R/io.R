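#' Write / read a trial log
#'
#' Trial logs are comma-separated UTF-8 text with a header row, one row per
#' trial, covering every phase (exposure, training, pulling test, familiarity
#' test). Writing is atomic (write-then-rename) and the write/read cycle is
#' an identity on the logged columns.
#'
#' @param trials A trial-log tibble.
#' @param path File path.
#' @return `write_trial_log()`: `path`, invisibly. `read_trial_log()`: the
#'   trial-log tibble.
#' @export
write_trial_log <- function(trials, path) {
  atomic_write(path, function(tmp) readr::write_csv(trials, tmp, progress = FALSE))
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  trials <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  num <- intersect(c("breakage_force_N", "pull_force_N"), names(trials))
  for (col in num) {
    bad <- !is.na(trials[[col]]) & (trials[[col]] < 0 | trials[[col]] > 40)
    if (any(bad)) stop("schema violation: forces outside [0, 40] N at row(s) ",
                       paste(head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  trials
}

#' Generate and summarize all designs for one experiment
#'
#' Builds the inventory and every phase design with the given seed, returning
#' the tables plus the headline counts (scene-enumeration categories for the
#' visual experiment, per-block compositions for the haptic one). When
#' `out_dir` is given, writes the inventory JSON and one CSV per phase.
#'
#' @param experiment `"visual_exposure"` or `"haptic_exposure"`.
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @return A list with `inventory`, `designs` (named list of tibbles) and
#'   `counts` (named list of summary counts).
#' @export
vhsl_design <- function(experiment = c("visual_exposure", "haptic_exposure"),
                        seed = 1, out_dir = NULL) {
  experiment <- match.arg(experiment)
  rng <- local_rng(seed)
  designs <- list()
  counts <- list()
  if (experiment == "visual_exposure") {
    inventory <- build_inventory(3, 3, seed = rng_child_seed(rng))
    scenes <- enumerate_exposure_scenes(inventory)
    designs$visual_exposure <-
      generate_visual_exposure_sequence(scenes, seed = rng_child_seed(rng))[
        , c("trial_index", "scene_code", "category")]
    counts$n_exposure_scenes <- nrow(scenes)
    counts$scene_categories <- table(scenes$category)
  } else {
    inventory <- build_inventory(2, 2, seed = rng_child_seed(rng))
    designs$haptic_exposure <- generate_haptic_exposure_design(
      inventory, n_blocks = 4, seed = rng_child_seed(rng))
    counts$n_exposure_trials <- nrow(designs$haptic_exposure)
  }
  designs$haptic_training <- generate_training_design(
    experiment, seed = rng_child_seed(rng))
  designs$haptic_pulling_test <- generate_pulling_test_design(
    experiment, inventory, seed = rng_child_seed(rng))
  designs$familiarity_test <- generate_familiarity_design(
    inventory, n_blocks = 2, seed = rng_child_seed(rng))
  counts$n_training_trials <- nrow(designs$haptic_training)
  counts$n_pulling_test_trials <- nrow(designs$haptic_pulling_test)
  counts$n_familiarity_trials <- nrow(designs$familiarity_test)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_inventory_json(inventory, file.path(out_dir, "inventory.json"))
    for (nm in names(designs)) {
      atomic_write(file.path(out_dir, paste0(nm, ".csv")), function(tmp) {
        readr::write_csv(designs[[nm]], tmp, progress = FALSE)
      })
    }
  }
  list(inventory = inventory, designs = designs, counts = counts)
}

#' Simulate a cohort and write its trial log
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `trial_log.csv`, `cohort.csv` (latent truth, minus the believed
#'   inventories) and `config.json`.
#' @return The [simulate_experiment()] result.
#' @export
vhsl_simulate <- function(config, out_dir = NULL) {
  sim <- simulate_experiment(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trial_log(sim$trials, file.path(out_dir, "trial_log.csv"))
    atomic_write(file.path(out_dir, "cohort.csv"), function(tmp) {
      readr::write_csv(sim$cohort[, setdiff(names(sim$cohort), "believed")],
                       tmp, progress = FALSE)
    })
    atomic_write(file.path(out_dir, "config.json"), function(tmp) {
      jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
    })
  }
  sim
}

#' End-to-end analysis of a trial log
#'
#' Runs the full analysis pipeline on a trial log: training-based exclusion,
#' per-participant performance measures, the rectified exponential-binomial
#' fit with likelihood-ratio test, Laplace Bayes factor, range coverage and
#' profile-likelihood band, the block-trend test on the generalisation test,
#' the within-participant object-consistency analysis, and — when
#' explicitness scores are supplied (or present in `debrief`) — the
#' explicitness partial-correlation analysis. Missing phases degrade
#' gracefully: the corresponding entries are `NULL` and listed in `skipped`.
#'
#' @param trials A trial-log tibble (one or both experiments).
#' @param debrief Optional debriefing tibble with `participant_id`,
#'   `noticed`, `n_correct_pairs`, `n_true_pairs`.
#' @param alpha Confidence level for the band (default 0.05).
#' @param n_band_samples Laplace samples for the band (default 1e5).
#' @param n_starts Optimizer starts for the model fit.
#' @param scale_r JZS prior scale.
#' @param seed Seed for the band sampling and fit starts.
#' @param band Compute the profile-likelihood band? (default TRUE)
#' @return A list of class `vhsl_report`.
#' @export
vhsl_analyze <- function(trials, debrief = NULL, alpha = 0.05,
                         n_band_samples = 1e5, n_starts = 20,
                         scale_r = sqrt(2) / 2, seed = 1, band = TRUE) {
  report <- list(skipped = character())
  skip <- function(what) report$skipped <<- c(report$skipped, what)

  perf <- participant_performance(trials)
  report$performance <- perf
  included <- perf[!perf$excluded, ]
  report$n_excluded <- sum(perf$excluded)

  fit_data <- included[!is.na(included$f_c) & included$rho_defined, ]
  if (nrow(fit_data) >= 3 && length(unique(fit_data$rho)) >= 2) {
    data <- tibble::tibble(rho = fit_data$rho, correct = fit_data$t_c,
                           trials = fit_data$t_total)
    full <- fit_refb(data, n_starts = n_starts, seed = seed)
    null <- fit_null(data)
    report$refb <- list(
      fit = full, null = null,
      lr = lr_test(full, null),
      log10_bf = tryCatch(laplace_log10_bf(full, null),
                          error = function(e) NA_real_),
      range_coverage = range_coverage(full$params),
      band = if (band) profile_ci_band(full, alpha = alpha,
                                       n_samples = n_band_samples,
                                       seed = seed) else NULL
    )
  } else {
    report$refb <- NULL
    skip("refb model (too few participants with defined measures)")
  }

  # Block trend on the generalisation test of each experiment present:
  # pulling blocks after visual exposure, familiarity blocks after haptic.
  trend <- list()
  for (ex in unique(perf$experiment)) {
    pe <- included[included$experiment %in% ex, ]
    tr <- tryCatch({
      if (identical(ex, "haptic_exposure")) {
        block_trend_test(pe$f_c_block1, pe$f_c_block2, scale_r)
      } else {
        block_trend_test(pe$rho_block1, pe$rho_block2, scale_r)
      }
    }, error = function(e) NULL)
    if (is.null(tr)) skip(paste0("block trend (", ex, ")")) else
      trend[[as.character(ex)]] <- tr
  }
  report$block_trend <- trend

  cons <- tryCatch({
    sc <- scene_scores(trials[trials$participant_id %in%
                                included$participant_id, ])
    oc <- object_consistency(sc)
    list(scores = sc, per_participant = oc,
         group = consistency_group_test(oc$consistency, scale_r))
  }, error = function(e) NULL)
  if (is.null(cons)) skip("object consistency") else report$consistency <- cons

  expl <- NULL
  if (!is.null(debrief)) {
    debrief$explicitness <- explicitness_score(
      debrief$noticed, debrief$n_correct_pairs, debrief$n_true_pairs)
    d <- dplyr::inner_join(
      included, debrief[, c("participant_id", "explicitness")],
      by = "participant_id")
    d <- tibble::tibble(visual = d$f_c, haptic = d$rho,
                        explicitness = d$explicitness,
                        experiment = d$experiment)
    expl <- tryCatch(explicitness_partial_analysis(d), error = function(e) NULL)
  }
  if (is.null(expl) && !is.null(debrief)) skip("explicitness analysis")
  report$explicitness <- expl
  class(report) <- "vhsl_report"
  report
}

#' @export
print.vhsl_report <- function(x, ...) {
  cat("<vhsl_report>\n")
  cat(sprintf("  participants: %d (%d excluded)\n",
              nrow(x$performance), x$n_excluded))
  if (!is.null(x$refb)) {
    cat(sprintf("  refb fit: beta0 %.3f beta1 %.3f lambda %.3f | chi2(2) %.1f, p %.2g | log10 BF %.1f | coverage %.0f%%\n",
                x$refb$fit$params[["beta0"]], x$refb$fit$params[["beta1"]],
                x$refb$fit$params[["lambda"]], x$refb$lr$chi2, x$refb$lr$p,
                x$refb$log10_bf, 100 * x$refb$range_coverage))
  }
  if (!is.null(x$consistency)) {
    g <- x$consistency$group
    cat(sprintf("  consistency: %.3f +/- %.3f, t(%d) = %.2f, p = %.3g, BF = %.1f\n",
                g$mean, g$sem, g$df, g$t, g$p, g$bf10))
  }
  if (!is.null(x$explicitness)) {
    e <- x$explicitness
    cat(sprintf("  explicitness: R_full %.2f, R_partial %.2f, implicit share %.0f%%\n",
                e$r_full, e$r_partial, 100 * e$variance_ratio))
  }
  if (length(x$skipped)) cat("  skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' @param report A `vhsl_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  obj <- list(
    n_participants = nrow(report$performance),
    n_excluded = report$n_excluded,
    skipped = report$skipped
  )
  if (!is.null(report$refb)) {
    obj$refb <- list(
      params = as.list(unlist(report$refb$fit$params)),
      loglik = report$refb$fit$loglik,
      chi2 = report$refb$lr$chi2, df = report$refb$lr$df, p = report$refb$lr$p,
      log10_bf = report$refb$log10_bf,
      range_coverage = report$refb$range_coverage
    )
  }
  if (!is.null(report$consistency)) obj$consistency <- as.list(report$consistency$group)
  if (!is.null(report$explicitness)) obj$explicitness <- as.list(report$explicitness)
  if (length(report$block_trend)) obj$block_trend <- lapply(report$block_trend, as.list)
  atomic_write(path, function(tmp) {
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA, na = "null")
  })
  invisible(path)
}

#' Parameter-recovery study for the rectified exponential-binomial
#'
#' Simulates replicate cohorts from known parameters, refits each, and
#' summarizes recovery: per-parameter bias (mean and median), RMSE, the
#' sup-norm error of the fitted curve over `rho` in \[0, 1\], and the
#' likelihood-ratio-test rejection rate at `alpha` (type-I error when
#' simulating under the null `beta1 = beta0`, power otherwise).
#'
#' @param params True [refb_params()].
#' @param n_replicates Number of simulated cohorts.
#' @param n_participants,n_trials Cohort size and familiarity trials per
#'   participant.
#' @param rho_range Uniform range for the simulated pulling correlations.
#' @param alpha LRT level (default 0.05).
#' @param n_starts Optimizer starts per fit.
#' @param seed Integer seed.
#' @return A list with `replicates` (per-replicate tibble) and `summary`
#'   (one-row tibble).
#' @export
vhsl_recover <- function(params, n_replicates = 200, n_participants = 20,
                         n_trials = 72, rho_range = c(-0.1, 0.9),
                         alpha = 0.05, n_starts = 20, seed = 1) {
  rng <- local_rng(seed)
  grid <- seq(0, 1, by = 0.01)
  p_true <- refb_probability(params, grid)
  rows <- lapply(seq_len(n_replicates), function(i) {
    data <- simulate_from_refb(params, n_participants, n_trials, rho_range,
                               seed = rng_child_seed(rng))
    full <- fit_refb(data, n_starts = n_starts, seed = rng_child_seed(rng))
    null <- fit_null(data)
    lr <- lr_test(full, null)
    tibble::tibble(
      replicate = i,
      beta0 = full$params[["beta0"]], beta1 = full$params[["beta1"]],
      lambda = full$params[["lambda"]],
      sup_norm = max(abs(refb_probability(full$params, grid) - p_true)),
      chi2 = lr$chi2, p = lr$p, reject = lr$p < alpha
    )
  })
  reps <- dplyr::bind_rows(rows)
  summ <- tibble::tibble(
    n_replicates = n_replicates,
    beta0_median_bias = stats::median(reps$beta0) - params[["beta0"]],
    beta1_median_bias = stats::median(reps$beta1) - params[["beta1"]],
    lambda_median_bias = stats::median(reps$lambda) - params[["lambda"]],
    beta0_rmse = sqrt(mean((reps$beta0 - params[["beta0"]])^2)),
    beta1_rmse = sqrt(mean((reps$beta1 - params[["beta1"]])^2)),
    median_sup_norm = stats::median(reps$sup_norm),
    rejection_rate = mean(reps$reject),
    low_precision = n_replicates < 20
  )
  list(replicates = reps, summary = summ)
}
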