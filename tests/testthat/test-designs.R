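test_that("haptic-exposure blocks cover the combination structure exactly", {
  inv <- build_inventory(2, 2, seed = 6)
  des <- generate_haptic_exposure_design(inv, n_blocks = 4, seed = 1)
  expect_equal(nrow(des), 192)
  for (b in 1:4) {
    blk <- des[des$block == b, ]
    expect_equal(nrow(blk), 48)
    comp <- table(paste(pmin(blk$kind_a, blk$kind_b),
                        pmax(blk$kind_a, blk$kind_b)), blk$breakage_force_N)
    expect_equal(unname(comp["true true", "22.5"]), 4)
    expect_equal(unname(comp["true true", "7.5"]), 4)
    expect_equal(unname(comp["pseudo pseudo", "7.5"]), 8)
    expect_equal(unname(comp["pseudo true", "15"]), 16)
    expect_equal(unname(comp["pseudo true", "7.5"]), 16)
    # every unordered same-orientation combination in both orders and
    # both directions, exactly once each
    key <- paste(blk$pair_a, blk$pair_b, blk$direction)
    expect_equal(anyDuplicated(key), 0L)
  }
  expect_identical(des, generate_haptic_exposure_design(inv, 4, seed = 1))
  expect_error(generate_haptic_exposure_design(build_inventory(3, 3, seed = 1),
                                               4, seed = 1),
               "invalid inventory")
})

test_that("pulling-test designs have the per-experiment structure", {
  inv3 <- build_inventory(3, 3, seed = 2)
  vis <- generate_pulling_test_design("visual_exposure", inv3, seed = 3)
  expect_equal(nrow(vis), 48)
  expect_true(all(vis$mode == "clamp_catch"))
  expect_true(all(vis$kind_a == "true" & vis$kind_b == "true"))
  expect_equal(length(unique(vis$scene_code)), 12)
  expect_setequal(unique(vis$block), 1:2)
  for (b in 1:2) {
    blk <- vis[vis$block == b, ]
    expect_equal(nrow(blk), 24)
    expect_equal(anyDuplicated(paste(blk$scene_code, blk$direction)), 0L)
  }
  expect_true(all(sort(unique(vis$breakage_force_N)) == c(7.5, 22.5)))

  inv2 <- build_inventory(2, 2, seed = 2)
  hap <- generate_pulling_test_design("haptic_exposure", inv2, seed = 3)
  expect_equal(nrow(hap), 48)
  expect_true(all(hap$mode == "clamp"))
  tt <- hap[hap$kind_a == "true" & hap$kind_b == "true", ]
  expect_equal(length(unique(tt$scene_code)), 4)
  expect_error(generate_pulling_test_design("visual_exposure", inv2, seed = 1),
               "invalid inventory")
})

test_that("familiarity blocks pair every true with every same-orientation pseudo in both orders", {
  for (sizes in list(c(3, 3), c(2, 2))) {
    inv <- build_inventory(sizes[1], sizes[2], seed = 4)
    block_size <- 2 * (sizes[1] * sizes[2] + sizes[2] * sizes[1])
    des <- generate_familiarity_design(inv, n_blocks = 2, seed = 5)
    expect_equal(nrow(des), 2 * block_size)
    for (b in 1:2) {
      blk <- des[des$block == b, ]
      expect_equal(nrow(blk), block_size)
      # exactly one true and one pseudo per trial, same orientation
      p <- inv$pairs
      kf <- p$kind[match(blk$first_pair, p$pair_id)]
      ks <- p$kind[match(blk$second_pair, p$pair_id)]
      expect_true(all(sort(c(kf, ks)) ==
                        rep(c("pseudo", "true"), each = block_size)))
      expect_true(all(p$orientation[match(blk$first_pair, p$pair_id)] ==
                        p$orientation[match(blk$second_pair, p$pair_id)]))
      # each (true, pseudo, order) exactly once
      expect_equal(anyDuplicated(paste(blk$true_pair, blk$pseudo_pair,
                                       blk$correct_position)), 0L)
    }
  }
})

test_that("true-pair appearance counts match the brute-force recount", {
  # Per 36-trial block each true pair meets its 3 same-orientation pseudo
  # pairs in both orders: 6 appearances; 12 over the standard 2-block test.
  inv <- build_inventory(3, 3, seed = 9)
  blk <- generate_familiarity_design(inv, n_blocks = 1, seed = 1)
  expect_true(all(table(blk$true_pair) == 6))
  full <- generate_familiarity_design(inv, n_blocks = 2, seed = 1)
  expect_true(all(table(full$true_pair) == 12))
  # every pair (true or pseudo) is shown equally often overall
  shown <- table(c(full$first_pair, full$second_pair))
  expect_true(all(shown == 12))
})

test_that("training designs hit the printed totals and compositions", {
  vis <- generate_training_design("visual_exposure", seed = 7)
  expect_equal(nrow(vis), 56)
  expect_equal(as.integer(table(vis$mode)[c("standard", "clamp", "clamp_catch")]),
               c(24, 16, 16))
  expect_true(all(vis$configuration == "C2"))
  hap <- generate_training_design("haptic_exposure", seed = 8)
  expect_equal(nrow(hap), 144)
  for (b in 1:3) {
    blk <- hap[hap$block == b, ]
    expect_equal(as.integer(table(blk$configuration)[c("C2", "C3", "C4")]),
                 c(8, 32, 8))
  }
  expect_equal(sum(hap$mode == "standard"), 96)
  expect_equal(sum(hap$mode == "clamp"), 48)
  # scenes are pulled in both directions on consecutive trials
  expect_true(all(tapply(vis$direction, rep(seq_len(28), each = 2),
                         function(d) length(unique(d))) == 2))
})
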