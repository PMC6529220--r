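test_that("scene scores match a longhand recount on a hand-built log", {
  # four unique two-true-pair scenes; per scene: hard-direction force h_i on
  # both repetitions, easy-direction force e_i on both; participant always
  # chooses true pairs in the familiarity test
  hard <- c(20, 25, 18, 22)
  easy <- c(10, 9, 11, 8)
  toy <- toy_consistency_log(hard, easy, function(pair_id) {
    pair_id %in% toy_inventory_true_ids()
  })
  sc <- scene_scores(toy$trials)
  expect_equal(nrow(sc), 4)
  ord <- match(unique(sort(sc$scene_code)), sc$scene_code)
  expect_setequal(round(sc$haptic_score, 10), round(hard - easy, 10))
  expect_true(all(sc$familiarity_score == 1))
  expect_true(all(sc$n_reps == 2))
})

test_that("a force-matching participant scores the force-table difference", {
  toy <- toy_consistency_log(rep(22.5, 4), rep(7.5, 4), function(pair_id) {
    pair_id %in% toy_inventory_true_ids()
  })
  sc <- scene_scores(toy$trials)
  expect_true(all(sc$haptic_score == 15))
})

test_that("object consistency flags undefined cases instead of zeroing them", {
  toy <- toy_consistency_log(c(20, 25, 18, 22), c(10, 9, 11, 8),
                             function(pair_id) {
                               pair_id %in% toy_inventory_true_ids()
                             })
  oc <- object_consistency(scene_scores(toy$trials))
  expect_false(oc$defined[1])  # familiarity at ceiling: zero variance
  expect_true(is.na(oc$consistency[1]))
})

test_that("object consistency is a Pearson correlation with affine invariance", {
  sc <- tibble::tibble(participant_id = 1L, scene_code = letters[1:4],
                       pair_a = 1L, pair_b = 2L,
                       haptic_score = c(1, 2, 3, 4),
                       familiarity_score = c(0.2, 0.4, 0.6, 0.8), n_reps = 2L)
  oc <- object_consistency(sc)
  expect_equal(oc$consistency, 1)
  sc2 <- sc
  sc2$haptic_score <- 3 * sc$haptic_score + 7  # rescale + offset forces
  expect_equal(object_consistency(sc2)$consistency, 1)
  sc3 <- sc
  sc3$familiarity_score <- rev(sc$familiarity_score)
  expect_equal(object_consistency(sc3)$consistency, -1)
})

test_that("swapped-inventory participants are consistent with the wrong objects", {
  # theta = 1, tiny noise, internal inventory with two h pairs swapped:
  # the participant's haptic and familiarity scene scores covary positively
  # even though their accuracy against the true inventory is reduced
  cfg <- cohort_config(n_participants = 8, sigma_pull = 2,
                       swap_probability = 1, theta_shape1 = 30,
                       theta_shape2 = 1, seed = 15,
                       experiment = "visual_exposure")
  sim <- simulate_experiment(cfg, phases = c("haptic_pulling_test",
                                             "familiarity_test"))
  oc <- object_consistency(scene_scores(sim$trials))
  expect_gt(mean(oc$consistency[oc$defined]), 0.3)
  # accuracy against the true inventory drops to chance on the swapped pairs
  fam <- sim$trials[sim$trials$phase == "familiarity_test", ]
  idx <- match(fam$participant_id, sim$cohort$participant_id)
  on_swapped <- fam$true_pair == sim$cohort$swap_a[idx] |
    fam$true_pair == sim$cohort$swap_b[idx]
  acc_swapped <- mean(fam$correct[on_swapped])
  acc_intact <- mean(fam$correct[!on_swapped])
  expect_gt(acc_intact, acc_swapped)
  expect_lt(abs(acc_swapped - 0.5), 0.15)  # chance-level on swapped pairs
})

test_that("the group consistency test has its fixed points", {
  zeros <- rep(0, 6)
  res <- consistency_group_test(zeros)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  x <- c(0.2, 0.4, 0.1, 0.5, 0.3, NA)
  res2 <- consistency_group_test(x)
  tt <- t.test(x[!is.na(x)])
  expect_equal(res2$t, unname(tt$statistic))
  expect_equal(res2$n, 5)
  expect_error(consistency_group_test(c(0.2, NA)), "insufficient data")
})

test_that("explicitness scores follow the debriefing rules", {
  expect_equal(explicitness_score(FALSE, 0, 6), 0)
  expect_equal(explicitness_score(TRUE, 3, 6), 0.5)
  expect_equal(explicitness_score(TRUE, 4, 4), 1)
  expect_equal(explicitness_score(c(FALSE, TRUE), c(0, 2), c(6, 4)),
               c(0, 0.5))
  expect_error(explicitness_score(TRUE, 7, 6), "record error")
})

test_that("constant explicitness leaves the partial correlation unchanged", {
  set.seed(23)
  n <- 24
  d <- tibble::tibble(
    haptic = runif(n, -0.1, 0.9),
    experiment = rep(c("visual_exposure", "haptic_exposure"), each = n / 2),
    explicitness = 0.5,
    visual = 0.5 + 0.4 * haptic + ifelse(experiment == "visual_exposure",
                                         0.05, 0) + rnorm(n, 0, 0.05)
  )
  res <- explicitness_partial_analysis(d)
  expect_equal(res$r_partial, res$r_full, tolerance = 1e-10)
  expect_equal(res$variance_ratio, 1, tolerance = 1e-10)
  expect_gt(res$r_full, 0.5)
})

test_that("full mediation by explicitness annihilates the partial correlation", {
  set.seed(29)
  n <- 60
  expl <- sample(seq(0, 1, by = 1 / 6), n, replace = TRUE)
  d <- tibble::tibble(
    experiment = rep(c("visual_exposure", "haptic_exposure"), each = n / 2),
    explicitness = expl,
    haptic = 0.1 + 0.7 * expl + rnorm(n, 0, 0.03),
    visual = 0.5 + 0.45 * expl + rnorm(n, 0, 0.03)
  )
  res <- explicitness_partial_analysis(d)
  expect_gt(res$r_full, 0.8)
  expect_lt(abs(res$r_partial), 2 / sqrt(n))
  expect_lt(res$variance_ratio, 0.1)
})

test_that("single-experiment input falls back to a plain correlation", {
  set.seed(31)
  d <- tibble::tibble(
    experiment = "visual_exposure",
    explicitness = runif(10),
    haptic = runif(10),
    visual = runif(10)
  )
  expect_warning(res <- explicitness_partial_analysis(d), "single-experiment")
  expect_true(is.finite(res$r_full))
})
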