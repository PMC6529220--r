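test_that("cohort sampling is reproducible and respects the swap setting", {
  inv <- build_inventory(2, 2, seed = 1)
  cfg <- cohort_config(n_participants = 12, swap_probability = 0,
                       experiment = "haptic_exposure", seed = 5)
  a <- sample_cohort(cfg, inv)
  b <- sample_cohort(cfg, inv)
  expect_equal(a[, setdiff(names(a), "believed")],
               b[, setdiff(names(b), "believed")])
  expect_true(all(!a$swapped))
  expect_true(all(vapply(a$believed, identical, logical(1), inv)))
  cfg2 <- cohort_config(n_participants = 200, swap_probability = 1,
                        experiment = "haptic_exposure", seed = 6)
  c2 <- sample_cohort(cfg2, inv)
  expect_true(all(c2$swapped))
  # symmetric Beta gives mean theta near 0.5
  expect_lt(abs(mean(c2$theta) - 0.5), 3 * 0.5 / sqrt(2 * 2.5 + 1) / sqrt(200))
  expect_error(cohort_config(theta_shape1 = -1), "config error")
  expect_error(cohort_config(p_max = 1.5), "config error")
})

test_that("pulling forces follow the learning-weighted mixture", {
  inv <- build_inventory(2, 2, seed = 2)
  trials <- generate_pulling_test_design("haptic_exposure", inv, seed = 3)
  cohort <- sample_cohort(cohort_config(n_participants = 1, seed = 1,
                                        experiment = "haptic_exposure",
                                        swap_probability = 0,
                                        sigma_pull = 0), inv)
  naive <- cohort
  naive$theta <- 0
  f0 <- simulate_pull_forces(naive[1, ], trials, inv, rng = local_rng(1))
  expect_true(all(f0 == 7.5))  # naive participant pulls the separation force
  perfect <- cohort
  perfect$theta <- 1
  f1 <- simulate_pull_forces(perfect[1, ], trials, inv, rng = local_rng(1))
  expect_equal(f1, trials$breakage_force_N)
  # cross-modal attenuation shrinks forces toward the naive level
  f_cm <- simulate_pull_forces(perfect[1, ], trials, inv, cross_modal = TRUE,
                               rng = local_rng(1))
  expect_equal(f_cm, 0.2 * 7.5 + 0.8 * trials$breakage_force_N)
})

test_that("a swapped-inventory participant pulls by the swapped force table", {
  inv <- build_inventory(2, 2, seed = 4)
  tp <- inv$pairs[inv$pairs$kind == "true" & inv$pairs$orientation == "h", ]
  believed <- swap_true_pairs(inv, tp$pair_id[1], tp$pair_id[2])
  trials <- generate_pulling_test_design("haptic_exposure", inv, seed = 5)
  p <- sample_cohort(cohort_config(n_participants = 1, sigma_pull = 0,
                                   swap_probability = 0, seed = 1,
                                   experiment = "haptic_exposure"), inv)
  p$theta <- 1
  p$believed <- list(believed)
  f <- simulate_pull_forces(p[1, ], trials, inv, rng = local_rng(1))
  # independent oracle: per-trial contact sums under the believed object map
  expected <- vapply(seq_len(nrow(trials)), function(i) {
    sc <- parse_scene_code(trials$scene_code[i])
    breakage_force(sc, trials$direction[i], object_map(sc, inv, believed))
  }, numeric(1))
  expect_equal(f, expected)
  # the swap must actually change some forces relative to the true table
  expect_true(any(f != trials$breakage_force_N))
})

test_that("familiarity choices follow the closed-form link probability", {
  inv <- build_inventory(3, 3, seed = 3)
  cfg <- cohort_config(n_participants = 1, swap_probability = 0, seed = 2,
                       p_max = 0.95, lambda_gen = 0.3)
  p <- sample_cohort(cfg, inv)
  fam <- generate_familiarity_design(inv, n_blocks = 2, seed = 4)
  p$theta <- 0
  ch0 <- simulate_familiarity_choices(p[1, ], fam, inv, 0.95, 0.3,
                                      rng = local_rng(9))
  # theta = 0: exactly chance; over many trials the rate stays near 0.5
  big <- fam[rep(seq_len(nrow(fam)), 139), ]  # ~10,000 trials
  ch_big <- simulate_familiarity_choices(p[1, ], big, inv, 0.95, 0.3,
                                         rng = local_rng(10))
  expect_lt(abs(mean(ch_big$correct) - 0.5), 2 * sqrt(0.25 / nrow(big)))
  # theta = 0.6: empirical rate within 2 s.e. of the closed form
  p$theta <- 0.6
  pc <- 0.5 + (0.95 - 0.5) * (1 - exp(-0.6 / 0.3))
  ch1 <- simulate_familiarity_choices(p[1, ], big, inv, 0.95, 0.3,
                                      rng = local_rng(11))
  expect_lt(abs(mean(ch1$correct) - pc), 2 * sqrt(pc * (1 - pc) / nrow(big)))
})

test_that("simulated experiments have the printed per-participant row counts", {
  vis <- simulate_experiment(cohort_config(n_participants = 2, seed = 3,
                                           experiment = "visual_exposure"))
  per <- table(vis$trials$phase[vis$trials$participant_id == 1])
  expect_equal(as.integer(per[c("visual_exposure", "haptic_training",
                            "haptic_pulling_test", "familiarity_test")]),
               c(444, 56, 48, 72))
  hap <- simulate_experiment(cohort_config(n_participants = 2, seed = 3,
                                           experiment = "haptic_exposure"))
  per <- table(hap$trials$phase[hap$trials$participant_id == 1])
  expect_equal(as.integer(per[c("haptic_training", "haptic_exposure",
                            "haptic_pulling_test", "familiarity_test")]),
               c(144, 192, 48, 32))
  # byte-identical reruns
  vis2 <- simulate_experiment(cohort_config(n_participants = 2, seed = 3,
                                            experiment = "visual_exposure"))
  expect_identical(vis$trials, vis2$trials)
})

test_that("stronger learners do better on both tasks, and clipping is reported", {
  cfg <- cohort_config(n_participants = 24, seed = 8, swap_probability = 0,
                       sigma_pull = 3, experiment = "visual_exposure")
  sim <- simulate_experiment(cfg, phases = c("haptic_pulling_test",
                                             "familiarity_test"))
  perf <- participant_performance(sim$trials)
  ord <- order(sim$cohort$theta)
  expect_gt(cor(sim$cohort$theta, perf$rho[match(sim$cohort$participant_id,
                                                 perf$participant_id)]), 0.5)
  expect_gt(cor(sim$cohort$theta, perf$f_c[match(sim$cohort$participant_id,
                                                 perf$participant_id)]), 0.3)
  # zero noise, forces <= 22.5: nothing at the 40 N cap
  cfg0 <- cohort_config(n_participants = 4, seed = 9, sigma_pull = 0,
                        swap_probability = 0, experiment = "visual_exposure")
  sim0 <- simulate_experiment(cfg0, phases = c("haptic_pulling_test",
                                               "familiarity_test"))
  perf0 <- participant_performance(sim0$trials)
  expect_true(all(perf0$clipped_fraction == 0))
})

test_that("cross-modal attenuation lowers familiarity after haptic exposure", {
  common <- list(n_participants = 30, seed = 12, swap_probability = 0,
                 transfer_gain = 0.6)
  vis <- simulate_experiment(do.call(cohort_config,
                                     c(common, experiment = "visual_exposure")),
                             phases = "familiarity_test")
  hap <- simulate_experiment(do.call(cohort_config,
                                     c(common, experiment = "haptic_exposure")),
                             phases = "familiarity_test")
  f_vis <- mean(vis$trials$correct)
  f_hap <- mean(hap$trials$correct)
  expect_gt(f_vis, f_hap)
})

test_that("direct model simulation matches its binomial oracle", {
  p <- refb_params(0.5, 0.5, 1)
  d <- simulate_from_refb(p, 2000, 10, c(-0.5, 0.5), seed = 3)
  expect_lt(abs(sum(d$correct) / sum(d$trials) - 0.5),
            2 * sqrt(0.25 / sum(d$trials)))
  # rectification: all rho <= 0 draws succeed at rate beta0
  p2 <- refb_params(0.7, 0.95, 0.2)
  d2 <- simulate_from_refb(p2, 3000, 10, c(-0.6, -0.1), seed = 4)
  expect_lt(abs(sum(d2$correct) / sum(d2$trials) - 0.7),
            2 * sqrt(0.7 * 0.3 / sum(d2$trials)))
  # fixed rho: mean success matches P(rho) within 2 s.e. over 5000 draws
  d3 <- simulate_from_refb(p2, 5000, 1, c(0.4, 0.4), seed = 5)
  pr <- refb_probability(p2, 0.4)
  expect_lt(abs(mean(d3$correct) - pr), 2 * sqrt(pr * (1 - pr) / 5000))
})
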