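#' Cohort configuration
#'
#' Parameters of the invented generative model used to simulate behavioral
#' cohorts with a known latent structure. Each participant carries a learning
#' strength `theta` in \[0, 1\] drawn from a Beta distribution; `theta` drives
#' both pulling forces (a mixture of the naive separation force and the
#' subjective breakage force) and familiarity choices (through a saturating
#' exponential link), so the across-task correlation seen in real cohorts is
#' reproduced by construction. With probability `swap_probability` a
#' participant internalizes a *wrong* inventory in which two same-orientation
#' true pairs have exchanged a shape; such participants behave consistently
#' with their internal inventory across both tasks.
#'
#' @param n_participants Cohort size (default 20).
#' @param theta_shape1,theta_shape2 Beta parameters for the learning-strength
#'   distribution (default Beta(1.5, 1.5): broad, spanning poor to near-perfect
#'   learners).
#' @param sigma_pull Standard deviation of pulling-force noise in newtons
#'   (default 4).
#' @param p_max Asymptotic familiarity accuracy as learning saturates
#'   (default 0.95).
#' @param lambda_gen Rate constant of the generative familiarity link
#'   (default 0.3).
#' @param transfer_gain Multiplicative attenuation of `theta` when a task
#'   probes the modality *not* experienced during exposure (default 0.8).
#' @param swap_probability Probability of internalizing a pair-swapped
#'   inventory (default 0.1).
#' @param explicit_rate Scales the chance that a learned pair is also
#'   explicitly reportable at debriefing (default 0.5).
#' @param experiment `"visual_exposure"` or `"haptic_exposure"`.
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 20,
                          theta_shape1 = 1.5, theta_shape2 = 1.5,
                          sigma_pull = 4, p_max = 0.95, lambda_gen = 0.3,
                          transfer_gain = 0.8, swap_probability = 0.1,
                          explicit_rate = 0.5,
                          experiment = c("visual_exposure", "haptic_exposure"),
                          seed = 1) {
  experiment <- match.arg(experiment)
  if (n_participants < 1) stop("config error: n_participants must be >= 1.",
                               call. = FALSE)
  if (theta_shape1 <= 0 || theta_shape2 <= 0 || sigma_pull < 0 ||
      lambda_gen <= 0) {
    stop("config error: invalid distribution parameters.", call. = FALSE)
  }
  probs <- c(p_max, transfer_gain, swap_probability, explicit_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("config error: probabilities must lie in [0, 1].", call. = FALSE)
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Sample a cohort of latent participants
#'
#' @param config A [cohort_config()].
#' @param inventory The generative `vhsl_inventory` for the experiment.
#' @return A tibble with one row per participant: `participant_id`, `theta`,
#'   `sigma_pull`, `transfer_gain`, `explicit_rate`, `swapped`, `swap_a`,
#'   `swap_b` (the true pairs whose shapes were exchanged, `NA` if none),
#'   `explicit_n_correct` and `explicitness`, plus a `believed` list-column
#'   holding each participant's internal inventory.
#' @export
sample_cohort <- function(config, inventory) {
  rng <- local_rng(config$seed)
  n <- config$n_participants
  theta <- rng_rbeta(rng, n, config$theta_shape1, config$theta_shape2)
  swapped <- rng_runif(rng, n) < config$swap_probability
  tp <- inventory$pairs[inventory$pairs$kind == "true", ]
  n_true <- nrow(tp)
  pick_swap <- function() {
    o <- rng_sample(rng, c("h", "v"), size = 1)
    rng_sample(rng, tp$pair_id[tp$orientation == o], size = 2)
  }
  swaps <- lapply(seq_len(n), function(i) if (swapped[i]) pick_swap() else c(NA, NA))
  believed <- lapply(seq_len(n), function(i) {
    if (swapped[i]) swap_true_pairs(inventory, swaps[[i]][1], swaps[[i]][2])
    else inventory
  })
  # Debriefing: each true pair is explicitly reportable with probability
  # theta * explicit_rate, giving scores on the 0..1 grid of 1/n_true steps.
  n_correct <- rng_rbinom(rng, n, n_true, pmin(1, theta * config$explicit_rate))
  tibble::tibble(
    participant_id = seq_len(n),
    theta = theta,
    sigma_pull = config$sigma_pull,
    transfer_gain = config$transfer_gain,
    explicit_rate = config$explicit_rate,
    swapped = swapped,
    swap_a = vapply(swaps, `[`, numeric(1), 1),
    swap_b = vapply(swaps, `[`, numeric(1), 2),
    explicit_n_correct = n_correct,
    explicitness = n_correct / n_true,
    believed = believed
  )
}

# --- internal force/choice machinery -------------------------------------

# Is each real pair, as displayed in its own arrangement, a true pair of the
# believed inventory?
believed_intact <- function(inventory, believed) {
  p <- inventory$pairs
  bt <- believed$pairs[believed$pairs$kind == "true", ]
  key <- function(f, s, o) paste(f, s, o)
  key(p$first, p$second, p$orientation) %in% key(bt$first, bt$second, bt$orientation)
}

# Subjective breakage force for two-pair 2x2 scenes under a believed
# inventory, vectorized over trials. Parallel pulls cross each pair's internal
# contact; orthogonal pulls cross the two between-pair contacts, whose shapes
# could in principle form believed pairs of the orthogonal orientation.
internal_pair_force <- function(pair_a, pair_b, orientation, direction,
                                inventory, believed, config = bond_config()) {
  p <- inventory$pairs
  intact <- believed_intact(inventory, believed)
  names(intact) <- p$pair_id
  bw <- function(id) ifelse(intact[as.character(id)], config$intra_object,
                            config$inter_object)
  bt <- believed$pairs[believed$pairs$kind == "true", ]
  bkey <- paste(bt$first, bt$second, bt$orientation)
  ia <- match(pair_a, p$pair_id); ib <- match(pair_b, p$pair_id)
  cross_or <- ifelse(orientation == "h", "v", "h")
  cross1 <- paste(p$first[ia], p$first[ib], cross_or) %in% bkey
  cross2 <- paste(p$second[ia], p$second[ib], cross_or) %in% bkey
  cross_force <- ifelse(cross1, config$intra_object, config$inter_object) +
    ifelse(cross2, config$intra_object, config$inter_object)
  parallel <- (orientation == "h") == (direction == "horizontal")
  ifelse(parallel, bw(pair_a) + bw(pair_b), cross_force)
}

#' Simulate pulling forces for a set of pull trials
#'
#' The generated force is a learning-weighted mixture of the naive separation
#' force (`2 * inter_object`, what a participant with no knowledge of the
#' scene's composition would pull) and the participant's *subjective* breakage
#' force computed from their internal inventory, plus Gaussian motor noise,
#' clipped to \[0, `force_cap`\]:
#' `force = (1 - theta_eff) * 2 * inter + theta_eff * B_int + noise`.
#' `theta_eff = theta * transfer_gain` when the pull probes knowledge acquired
#' in the other modality (the pulling test of the visual-exposure experiment),
#' and `theta` otherwise.
#'
#' @param participant One row of a [sample_cohort()] tibble.
#' @param trials A pull-trial design tibble (with `pair_a`, `pair_b`,
#'   `orientation`, `direction`).
#' @param inventory The generative inventory.
#' @param cross_modal Is this phase a cross-modal probe?
#' @param config A [bond_config()].
#' @param rng An RNG stream from `local_rng()`.
#' @return Numeric vector of clipped pulling forces (newtons).
#' @export
simulate_pull_forces <- function(participant, trials, inventory,
                                 cross_modal = FALSE, config = bond_config(),
                                 rng = local_rng(1)) {
  theta_eff <- participant$theta * (if (cross_modal) participant$transfer_gain else 1)
  b_int <- internal_pair_force(trials$pair_a, trials$pair_b,
                               trials$orientation, trials$direction,
                               inventory, participant$believed[[1]], config)
  naive <- 2 * config$inter_object
  force <- (1 - theta_eff) * naive + theta_eff * b_int +
    rng_rnorm(rng, nrow(trials), 0, participant$sigma_pull)
  pmin(pmax(force, 0), config$force_cap)
}

#' Simulate familiarity choices for a set of familiarity trials
#'
#' The pair that is a true pair *of the participant's internal inventory* is
#' chosen with probability
#' `0.5 + (p_max - 0.5) * (1 - exp(-theta_eff / lambda_gen))`; when neither
#' (or both) displayed pairs are internally true the choice is uniform.
#' `theta_eff = theta * transfer_gain` when familiarity follows haptic-only
#' exposure, `theta` otherwise.
#'
#' @inheritParams simulate_pull_forces
#' @param trials A familiarity design tibble (with `first_pair`,
#'   `second_pair`).
#' @param p_max,lambda_gen Link parameters (see [cohort_config()]).
#' @return A tibble with `choice` (`"first"`/`"second"`) and `correct`
#'   (chose the generative true pair).
#' @export
simulate_familiarity_choices <- function(participant, trials, inventory,
                                         p_max, lambda_gen,
                                         cross_modal = FALSE,
                                         rng = local_rng(1)) {
  theta_eff <- participant$theta * (if (cross_modal) participant$transfer_gain else 1)
  p_choose <- 0.5 + (p_max - 0.5) * (1 - exp(-theta_eff / lambda_gen))
  intact <- believed_intact(inventory, participant$believed[[1]])
  names(intact) <- inventory$pairs$pair_id
  first_true <- intact[as.character(trials$first_pair)]
  second_true <- intact[as.character(trials$second_pair)]
  p_first <- ifelse(first_true & !second_true, p_choose,
                    ifelse(second_true & !first_true, 1 - p_choose, 0.5))
  choice <- ifelse(rng_runif(rng, nrow(trials)) < p_first, "first", "second")
  tibble::tibble(choice = choice,
                 correct = choice == trials$correct_position)
}

#' Simulate a full experiment
#'
#' Generates the complete phase sequence of one experiment for a synthetic
#' cohort: designs from the design generators, bond-model force annotations,
#' and simulated responses from the latent-participant model. Every stage is
#' seeded from the cohort configuration, so two runs with the same config are
#' identical.
#'
#' @param config A [cohort_config()].
#' @param phases Character vector of phases to simulate (default: all phases
#'   of the experiment). Restricting phases is useful for large simulation
#'   studies that only analyze the test phases.
#' @param config_bond A [bond_config()].
#' @return A list of class `vhsl_simulation`: `trials` (the trial-log tibble),
#'   `cohort`, `inventory`, `config`.
#' @export
simulate_experiment <- function(config, phases = NULL,
                                config_bond = bond_config()) {
  experiment <- config$experiment
  all_phases <- if (experiment == "visual_exposure") {
    c("visual_exposure", "haptic_training", "haptic_pulling_test",
      "familiarity_test")
  } else {
    c("haptic_training", "haptic_exposure", "haptic_pulling_test",
      "familiarity_test")
  }
  phases <- phases %||% all_phases
  rng <- local_rng(config$seed)
  inv_seed <- rng_child_seed(rng)
  inventory <- if (experiment == "visual_exposure") {
    build_inventory(3, 3, seed = inv_seed)
  } else {
    build_inventory(2, 2, seed = inv_seed)
  }
  cohort <- sample_cohort(config, inventory)
  exposure_scenes <- if (experiment == "visual_exposure" &&
                           "visual_exposure" %in% phases) {
    enumerate_exposure_scenes(inventory)
  } else NULL

  sim_one <- function(i) {
    p <- cohort[i, ]
    prng <- local_rng(rng_child_seed(rng))
    logs <- list()
    if ("visual_exposure" %in% phases && experiment == "visual_exposure") {
      seq_ <- generate_visual_exposure_sequence(exposure_scenes,
                                                seed = rng_child_seed(prng))
      logs$exposure <- tibble::tibble(
        phase = "visual_exposure", block = 1L,
        trial_index = seq_$trial_index, mode = "view",
        scene_code = seq_$scene_code
      )
    }
    if ("haptic_training" %in% phases) {
      tr <- generate_training_design(experiment, seed = rng_child_seed(prng),
                                     config = config_bond)
      # Boundaries are visibly coloured in training, so the subjective force
      # equals the true breakage force for every participant.
      noise <- rng_rnorm(prng, nrow(tr), 0, p$sigma_pull)
      tr$pull_force_N <- pmin(pmax(tr$breakage_force_N + noise, 0),
                              config_bond$force_cap)
      logs$training <- tr
    }
    if ("haptic_exposure" %in% phases && experiment == "haptic_exposure") {
      ex <- generate_haptic_exposure_design(inventory, n_blocks = 4,
                                            seed = rng_child_seed(prng),
                                            config = config_bond)
      # Standard trials end at the actual breakage threshold (full feedback).
      ex$pull_force_N <- ex$breakage_force_N
      logs$haptic_exposure <- ex
    }
    if ("haptic_pulling_test" %in% phases) {
      pt <- generate_pulling_test_design(experiment, inventory,
                                         seed = rng_child_seed(prng),
                                         config = config_bond)
      pt$pull_force_N <- simulate_pull_forces(
        p, pt, inventory, cross_modal = (experiment == "visual_exposure"),
        config = config_bond, rng = prng
      )
      logs$pulling_test <- pt
    }
    if ("familiarity_test" %in% phases) {
      fam <- generate_familiarity_design(
        inventory, n_blocks = 2, seed = rng_child_seed(prng)
      )
      resp <- simulate_familiarity_choices(
        p, fam, inventory, config$p_max, config$lambda_gen,
        cross_modal = (experiment == "haptic_exposure"), rng = prng
      )
      logs$familiarity <- dplyr::bind_cols(fam, resp)
    }
    out <- dplyr::bind_rows(logs)
    out$participant_id <- p$participant_id
    out
  }
  trials <- dplyr::bind_rows(lapply(seq_len(config$n_participants), sim_one))
  trials$experiment <- experiment
  trials <- dplyr::relocate(trials, "participant_id", "experiment")
  structure(list(trials = trials, cohort = cohort, inventory = inventory,
                 config = config),
            class = "vhsl_simulation")
}

#' @export
print.vhsl_simulation <- function(x, ...) {
  cat(sprintf("<vhsl_simulation> %s: %d participants, %d trial rows\n",
              x$config$experiment, nrow(x$cohort), nrow(x$trials)))
  print(dplyr::count(x$trials, .data$phase))
  invisible(x)
}

#' Simulate participants directly from the rectified exponential-binomial
#'
#' Draws per-participant pulling correlations uniformly on `rho_range` and
#' correct-trial counts `T_c ~ Binomial(P(rho), T)` under the rectified
#' exponential-binomial success probability. Used for parameter-recovery and
#' calibration studies of the model itself.
#'
#' @param params A [refb_params()].
#' @param n_participants Number of simulated participants.
#' @param n_trials Familiarity trials per participant (`T`).
#' @param rho_range Interval for the uniform draw of `rho` (within \[-1, 1\]).
#' @param seed Integer seed.
#' @return A tibble with `rho`, `correct` (`T_c`) and `trials` (`T`).
#' @export
simulate_from_refb <- function(params, n_participants, n_trials,
                               rho_range = c(-0.1, 0.9), seed = 1) {
  stopifnot(length(rho_range) == 2, rho_range[1] >= -1, rho_range[2] <= 1,
            rho_range[1] <= rho_range[2])
  rng <- local_rng(seed)
  rho <- rng_runif(rng, n_participants, rho_range[1], rho_range[2])
  p <- refb_probability(params, rho)
  tibble::tibble(
    rho = rho,
    correct = rng_rbinom(rng, n_participants, n_trials, p),
    trials = as.integer(n_trials)
  )
}
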