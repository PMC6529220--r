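#' Bond-model configuration
#'
#' Forces holding a scene together are simulated as bonds between edge-sharing
#' pieces: pieces of the same object attach with `intra_object` newtons and
#' pieces of different objects with `inter_object` newtons. The breakage force
#' of a pull is the sum of bond strengths crossing the split line. The robot
#' can generate at most `force_cap` N (pulling forces are clipped there) and a
#' pull is considered started once it exceeds `pull_threshold` N.
#'
#' @param intra_object,inter_object Bond strengths in newtons (defaults 11.25
#'   and 3.75, giving the canonical 7.5 / 15 / 22.5 N force levels).
#' @param force_cap Maximum recordable pulling force (default 40 N).
#' @param pull_threshold Pull-onset threshold (default 5 N).
#' @return A list of class `bond_config`.
#' @export
bond_config <- function(intra_object = 11.25, inter_object = 3.75,
                        force_cap = 40, pull_threshold = 5) {
  stopifnot(intra_object > 0, inter_object > 0, force_cap > 0,
            pull_threshold > 0, intra_object > inter_object)
  structure(list(intra_object = intra_object, inter_object = inter_object,
                 force_cap = force_cap, pull_threshold = pull_threshold),
            class = "bond_config")
}

#' Object map of a scene
#'
#' Assigns an object id to every occupied cell. True pairs behave as one
#' object spanning both cells; pseudo pairs behave haptically as two separate
#' single-shape objects, so each of their cells gets its own id. An optional
#' inventory override lets a simulated participant hold a *subjective* object
#' map: cells are grouped by the true-pair membership of the shapes they
#' contain under that inventory (two adjacent cells form one object only when
#' their shapes are a true pair of the given inventory in the displayed
#' arrangement).
#'
#' @param scene A scene tibble.
#' @param inventory The `vhsl_inventory` the scene was built from.
#' @param believed Optional `vhsl_inventory` describing the participant's
#'   internal inventory; defaults to `inventory` (veridical map).
#' @return A tibble with `row`, `col`, `shape`, `object` (character id).
#' @export
object_map <- function(scene, inventory, believed = inventory) {
  cells <- scene_cells(scene)
  p <- inventory$pairs
  idx <- match(cells$pair_id, p$pair_id)
  cells$shape <- ifelse(cells$slot == 1L, p$first[idx], p$second[idx])
  # Group cells into objects under the believed inventory: a believed true
  # pair (first, second) occupies one object iff its two shapes sit in the
  # displayed arrangement (first left-of second for h, first above second
  # for v); everything else is a single-shape object.
  bt <- believed$pairs[believed$pairs$kind == "true", ]
  cells$object <- paste0("s", cells$shape)
  for (i in seq_len(nrow(bt))) {
    a <- which(cells$shape == bt$first[i])
    b <- which(cells$shape == bt$second[i])
    if (length(a) != 1 || length(b) != 1) next
    ok <- if (bt$orientation[i] == "h") {
      cells$row[a] == cells$row[b] && cells$col[b] - cells$col[a] == 1L
    } else {
      cells$col[a] == cells$col[b] && cells$row[b] - cells$row[a] == 1L
    }
    if (ok) cells$object[c(a, b)] <- paste0("o", bt$pair_id[i])
  }
  cells[, c("row", "col", "shape", "object")]
}

#' Contacts crossed by the mid-line split of a 2 x 2 scene
#'
#' Horizontal pulling parts the scene into left/right halves (vertical
#' mid-line); vertical pulling parts it into top/bottom halves. For a 2 x 2
#' block the split always crosses exactly two cell contacts.
#'
#' @param scene A 2 x 2 scene tibble.
#' @param direction `"horizontal"` or `"vertical"` pulling.
#' @return A tibble with one row per crossed contact: `row_a`, `col_a`,
#'   `row_b`, `col_b` (the two cells either side of the split).
#' @export
split_contacts <- function(scene, direction = c("horizontal", "vertical")) {
  direction <- match.arg(direction)
  cells <- scene_cells(canonicalize(scene))
  if (nrow(cells) != 4 || max(cells$row) != 1 || max(cells$col) != 1) {
    stop("unsupported scene: mid-line splits are defined for 2x2 scenes only.",
         call. = FALSE)
  }
  if (direction == "horizontal") {
    tibble::tibble(row_a = 0:1, col_a = 0L, row_b = 0:1, col_b = 1L)
  } else {
    tibble::tibble(row_a = 0L, col_a = 0:1, row_b = 1L, col_b = 0:1)
  }
}

#' Breakage force of a 2 x 2 scene
#'
#' Sums the bond strengths crossing the split line implied by the pulling
#' direction: `intra_object` where the two sides of a contact belong to the
#' same object, `inter_object` otherwise. With the default bond strengths this
#' reproduces the three canonical force levels: 22.5 N (two true pairs, pull
#' parallel to their boundary), 15 N (true + pseudo pair, parallel pull) and
#' 7.5 N (any orthogonal pull, or two pseudo pairs in any direction).
#'
#' @param scene A 2 x 2 scene tibble.
#' @param direction Pulling direction (`"horizontal"`/`"vertical"`).
#' @param objects An object map from [object_map()] for this scene.
#' @param config A [bond_config()].
#' @return Breakage force in newtons.
#' @export
breakage_force <- function(scene, direction, objects, config = bond_config()) {
  contacts <- split_contacts(scene, direction)
  obj_at <- function(r, c) objects$object[objects$row == r & objects$col == c]
  same <- vapply(seq_len(nrow(contacts)), function(i) {
    identical(obj_at(contacts$row_a[i], contacts$col_a[i]),
              obj_at(contacts$row_b[i], contacts$col_b[i]))
  }, logical(1))
  sum(ifelse(same, config$intra_object, config$inter_object))
}

#' Breakage forces for the 2 x 2 pair-scene force table
#'
#' Fast closed form of [breakage_force()] for standard two-pair scenes,
#' vectorized over trials: a pull parallel to the pairs' shared boundary
#' crosses each pair's internal contact (intra-object for a true pair,
#' inter-object for a pseudo pair); an orthogonal pull crosses two
#' between-pair contacts.
#'
#' @param kind_a,kind_b `"true"`/`"pseudo"` for the two pairs.
#' @param orientation Pair orientation (`"h"`/`"v"`).
#' @param direction Pulling direction (`"horizontal"`/`"vertical"`).
#' @param config A [bond_config()].
#' @return Breakage force(s) in newtons.
#' @export
pair_scene_force <- function(kind_a, kind_b, orientation, direction,
                             config = bond_config()) {
  parallel <- (orientation == "h") == (direction == "horizontal")
  bond <- function(kind) ifelse(kind == "true", config$intra_object,
                                config$inter_object)
  ifelse(parallel, bond(kind_a) + bond(kind_b), 2 * config$inter_object)
}

#' Breakage force of a training configuration
#'
#' Training scenes use distinctly coloured rectangles and squares on the same
#' 2 x 2 block: `C2` = two 2-by-1 rectangles, `C3` = one rectangle plus two
#' unit squares, `C4` = four unit squares. The same bond-sum rule applies, so
#' with defaults C2 is 22.5 N in the direction breaking both rectangles and
#' 7.5 N orthogonally, C3 is 15 N when the rectangle must break and 7.5 N
#' otherwise, and C4 is 7.5 N in either direction.
#'
#' @param configuration `"C2"`, `"C3"` or `"C4"`.
#' @param orientation Orientation of the rectangle(s) (`"h"`/`"v"`).
#' @param direction Pulling direction (`"horizontal"`/`"vertical"`).
#' @param config A [bond_config()].
#' @return Breakage force(s) in newtons (vectorized).
#' @export
training_breakage_force <- function(configuration, orientation, direction,
                                    config = bond_config()) {
  stopifnot(all(configuration %in% c("C2", "C3", "C4")),
            all(orientation %in% c("h", "v")),
            all(direction %in% c("horizontal", "vertical")))
  parallel <- (orientation == "h") == (direction == "horizontal")
  n_rect <- ifelse(configuration == "C2", 2L,
                   ifelse(configuration == "C3", 1L, 0L))
  n_rect_broken <- n_rect * as.integer(parallel)  # recycles either argument
  n_rect_broken * config$intra_object +
    (2L - n_rect_broken) * config$inter_object
}
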