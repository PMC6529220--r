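#' Design generators
#'
#' Each generator returns a tibble with one row per trial, fully annotated
#' (scene composition, pulling direction, trial mode, breakage force).
#' Pseudorandomization is a seeded uniform shuffle within each block; the
#' prescribed combinatorial structure of every block is covered exactly.
#'
#' @name trial-designs
NULL

pull_scene_code <- function(pair_a, pair_b, orientation) {
  ifelse(orientation == "h",
         sprintf("%dh@0,0;%dh@1,0", pair_a, pair_b),
         sprintf("%dv@0,0;%dv@0,1", pair_a, pair_b))
}

shuffle_within_block <- function(df, rng) {
  df <- df[order(df$block), ]
  split_idx <- split(seq_len(nrow(df)), df$block)
  idx <- unlist(lapply(split_idx, function(i) {
    if (length(i) > 1) i[rng_sample(rng, seq_along(i))] else i
  }), use.names = FALSE)
  df <- df[idx, ]
  df$trial_index <- stats::ave(seq_len(nrow(df)), df$block, FUN = seq_along)
  df
}

#' Pseudorandom order for the visual exposure stream
#'
#' @param scenes The scene table from [enumerate_exposure_scenes()].
#' @param seed Integer seed.
#' @return The scene table in seeded pseudorandom order, with a
#'   `trial_index` column.
#' @export
generate_visual_exposure_sequence <- function(scenes, seed) {
  stopifnot(nrow(scenes) > 0)
  rng <- local_rng(seed)
  out <- scenes[rng_sample(rng, seq_len(nrow(scenes))), ]
  out$trial_index <- seq_len(nrow(out))
  out
}

# All same-orientation two-pair scenes for the haptic exposure/test block:
# every unordered combination of the orientation's pairs, in both arrangement
# orders and both pulling directions.
haptic_block_grid <- function(pairs) {
  per_orientation <- function(o) {
    po <- pairs[pairs$orientation == o, ]
    combos <- utils::combn(seq_len(nrow(po)), 2)
    ordered <- cbind(combos, combos[2:1, , drop = FALSE])
    tidyr::expand_grid(
      i = seq_len(ncol(ordered)),
      direction = c("horizontal", "vertical")
    ) |>
      dplyr::mutate(
        pair_a = po$pair_id[ordered[1, .data$i]],
        pair_b = po$pair_id[ordered[2, .data$i]],
        kind_a = po$kind[ordered[1, .data$i]],
        kind_b = po$kind[ordered[2, .data$i]],
        orientation = o
      ) |>
      dplyr::select(-"i")
  }
  dplyr::bind_rows(per_orientation("h"), per_orientation("v"))
}

#' Haptic statistical exposure design
#'
#' Standard-trial blocks for the haptic exposure phase: within each 48-trial
#' block every unordered same-orientation combination of the 2 true + 2
#' pseudo pairs appears in both arrangement orders and both pulling
#' directions (8 true-true, 8 pseudo-pseudo and 32 mixed trials per block).
#'
#' @param inventory A `vhsl_inventory` with 2 true pairs per orientation.
#' @param n_blocks Number of blocks (default 4, i.e. 192 trials).
#' @param seed Integer seed for the within-block shuffles.
#' @param config A [bond_config()].
#' @return A trial tibble (`phase = "haptic_exposure"`, `mode = "standard"`).
#' @export
generate_haptic_exposure_design <- function(inventory, n_blocks = 4, seed,
                                            config = bond_config()) {
  if (inventory$n_true_h != 2 || inventory$n_true_v != 2) {
    stop("invalid inventory: haptic exposure needs 2 true pairs per ",
         "orientation (plus matching pseudo pairs).", call. = FALSE)
  }
  rng <- local_rng(seed)
  grid <- haptic_block_grid(inventory$pairs)
  out <- tidyr::expand_grid(block = seq_len(n_blocks), grid) |>
    dplyr::mutate(
      phase = "haptic_exposure", mode = "standard",
      scene_code = pull_scene_code(.data$pair_a, .data$pair_b, .data$orientation),
      breakage_force_N = pair_scene_force(.data$kind_a, .data$kind_b,
                                          .data$orientation, .data$direction,
                                          config)
    )
  shuffle_within_block(out, rng) |> relocate_design_cols()
}

#' Haptic pulling-test design
#'
#' In the visual-exposure experiment the test comprises two 24-trial blocks of
#' clamp-catch trials: each ordered same-orientation combination of two true
#' pairs once per block per pulling direction (12 unique scenes x 2
#' directions). In the haptic-exposure experiment it is a single 48-trial
#' clamp block with the composition of one haptic-exposure block.
#'
#' @param experiment `"visual_exposure"` or `"haptic_exposure"`.
#' @param inventory The matching `vhsl_inventory` (3+3 true pairs for
#'   `visual_exposure`; 2+2 true and pseudo pairs for `haptic_exposure`).
#' @param seed Integer seed.
#' @param config A [bond_config()].
#' @return A trial tibble (`phase = "haptic_pulling_test"`).
#' @export
generate_pulling_test_design <- function(experiment = c("visual_exposure",
                                                        "haptic_exposure"),
                                         inventory, seed,
                                         config = bond_config()) {
  experiment <- match.arg(experiment)
  rng <- local_rng(seed)
  if (experiment == "visual_exposure") {
    if (inventory$n_true_h != 3 || inventory$n_true_v != 3) {
      stop("invalid inventory: the visual-exposure pulling test needs 3 true ",
           "pairs per orientation.", call. = FALSE)
    }
    tp <- inventory$pairs[inventory$pairs$kind == "true", ]
    per_orientation <- function(o) {
      po <- tp[tp$orientation == o, ]
      g <- tidyr::expand_grid(a = seq_len(nrow(po)), b = seq_len(nrow(po)),
                              direction = c("horizontal", "vertical")) |>
        dplyr::filter(.data$a != .data$b)
      dplyr::mutate(g,
                    pair_a = po$pair_id[.data$a], pair_b = po$pair_id[.data$b],
                    kind_a = "true", kind_b = "true", orientation = o) |>
        dplyr::select(-"a", -"b")
    }
    grid <- dplyr::bind_rows(per_orientation("h"), per_orientation("v"))
    out <- tidyr::expand_grid(block = 1:2, grid) |>
      dplyr::mutate(mode = "clamp_catch")
  } else {
    if (inventory$n_true_h != 2 || inventory$n_true_v != 2) {
      stop("invalid inventory: the haptic-exposure pulling test needs 2 true ",
           "pairs per orientation.", call. = FALSE)
    }
    out <- haptic_block_grid(inventory$pairs) |>
      dplyr::mutate(block = 1L, mode = "clamp")
  }
  out <- out |>
    dplyr::mutate(
      phase = "haptic_pulling_test",
      scene_code = pull_scene_code(.data$pair_a, .data$pair_b, .data$orientation),
      breakage_force_N = pair_scene_force(.data$kind_a, .data$kind_b,
                                          .data$orientation, .data$direction,
                                          config)
    )
  shuffle_within_block(out, rng) |> relocate_design_cols()
}

#' Two-alternative familiarity-test design
#'
#' Within every block each true pair is compared to each pseudo pair of the
#' same orientation in each presentation order exactly once, so the block size
#' is `2 * sum over orientations of n_true * n_pseudo` (36 trials for a 3+3
#' inventory, 16 for a 2+2 inventory).
#'
#' @param inventory A `vhsl_inventory`.
#' @param n_blocks Number of blocks (2 in both standard designs).
#' @param seed Integer seed.
#' @return A trial tibble with `first_pair`, `second_pair`,
#'   `correct_position` (`"first"`/`"second"`, the true pair's slot).
#' @export
generate_familiarity_design <- function(inventory, n_blocks = 2, seed) {
  rng <- local_rng(seed)
  p <- inventory$pairs
  per_orientation <- function(o) {
    tp <- p$pair_id[p$kind == "true" & p$orientation == o]
    pp <- p$pair_id[p$kind == "pseudo" & p$orientation == o]
    tidyr::expand_grid(true_pair = tp, pseudo_pair = pp,
                       correct_position = c("first", "second")) |>
      dplyr::mutate(orientation = o)
  }
  grid <- dplyr::bind_rows(per_orientation("h"), per_orientation("v")) |>
    dplyr::mutate(
      first_pair = ifelse(.data$correct_position == "first",
                          .data$true_pair, .data$pseudo_pair),
      second_pair = ifelse(.data$correct_position == "first",
                           .data$pseudo_pair, .data$true_pair)
    )
  out <- tidyr::expand_grid(block = seq_len(n_blocks), grid) |>
    dplyr::mutate(phase = "familiarity_test")
  out <- shuffle_within_block(out, rng)
  dplyr::select(out, "phase", "block", "trial_index", "orientation",
                "first_pair", "second_pair", "true_pair", "pseudo_pair",
                "correct_position")
}

#' Haptic task-training design
#'
#' Training scenes are 2 x 2 blocks of distinctly coloured rectangles/squares
#' (configurations C2/C3/C4, see [training_breakage_force()]); each scene is
#' pulled in one direction and then, on the next trial, in the orthogonal
#' direction. The visual-exposure experiment trains with 56 C2 trials
#' (24 standard, then 16 clamp, then 16 clamp-catch). The haptic-exposure
#' experiment trains with 144 trials: two 48-trial standard blocks and one
#' 48-trial clamp block, each composed of 8 C2, 8 C4 and 32 C3 trials.
#'
#' @param experiment `"visual_exposure"` or `"haptic_exposure"`.
#' @param seed Integer seed.
#' @param config A [bond_config()].
#' @return A trial tibble (`phase = "haptic_training"`).
#' @export
generate_training_design <- function(experiment = c("visual_exposure",
                                                    "haptic_exposure"),
                                     seed, config = bond_config()) {
  experiment <- match.arg(experiment)
  rng <- local_rng(seed)
  scene_block <- function(n_c2, n_c3, n_c4, mode, block) {
    confs <- rng_sample(rng, rep(c("C2", "C3", "C4"), c(n_c2, n_c3, n_c4)))
    ors <- rng_sample(rng, c("h", "v"), size = length(confs), replace = TRUE)
    d1 <- rng_sample(rng, c("horizontal", "vertical"), size = length(confs),
                     replace = TRUE)
    tibble::tibble(
      block = block, mode = mode,
      configuration = rep(confs, each = 2L),
      orientation = rep(ors, each = 2L),
      direction = as.vector(rbind(d1, ifelse(d1 == "horizontal",
                                             "vertical", "horizontal")))
    )
  }
  out <- if (experiment == "visual_exposure") {
    dplyr::bind_rows(
      scene_block(12, 0, 0, "standard", 1L),
      scene_block(8, 0, 0, "clamp", 2L),
      scene_block(8, 0, 0, "clamp_catch", 3L)
    )
  } else {
    dplyr::bind_rows(
      scene_block(4, 16, 4, "standard", 1L),
      scene_block(4, 16, 4, "standard", 2L),
      scene_block(4, 16, 4, "clamp", 3L)
    )
  }
  out |>
    dplyr::mutate(
      phase = "haptic_training",
      trial_index = stats::ave(seq_len(nrow(out)), out$block, FUN = seq_along),
      scene_code = paste0(.data$configuration, .data$orientation),
      breakage_force_N = training_breakage_force(.data$configuration,
                                                 .data$orientation,
                                                 .data$direction, config)
    ) |>
    dplyr::select("phase", "block", "trial_index", "mode", "configuration",
                  "orientation", "direction", "scene_code", "breakage_force_N")
}

relocate_design_cols <- function(df) {
  dplyr::select(df, "phase", "block", "trial_index", "mode", "scene_code",
                "pair_a", "pair_b", "kind_a", "kind_b", "orientation",
                "direction", "breakage_force_N")
}
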