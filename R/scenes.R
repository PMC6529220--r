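#' Grid scenes
#'
#' A scene is a placement of pairs on a small rectangular grid, represented as
#' a tibble with one row per pair: `pair_id`, `orientation` ("h"/"v"),
#' `row`, `col` (the anchor, i.e. the pair's top-left cell; 0-based, row 0 at
#' top). A horizontal pair occupies `(row, col)` and `(row, col + 1)`; a
#' vertical pair occupies `(row, col)` and `(row + 1, col)`.
#'
#' @name grid-scenes
NULL

new_scene <- function(pair_id, orientation, row, col) {
  tibble::tibble(pair_id = as.integer(pair_id), orientation = orientation,
                 row = as.integer(row), col = as.integer(col))
}

#' Cells occupied by a scene
#'
#' @param scene A scene tibble (see [grid-scenes]).
#' @return A tibble with one row per occupied cell: `pair_id`, `slot` (1 =
#'   anchor shape, 2 = the other), `row`, `col`.
#' @export
scene_cells <- function(scene) {
  dh <- scene$orientation == "h"
  tibble::tibble(
    pair_id = rep(scene$pair_id, each = 2L),
    slot = rep(1:2, times = nrow(scene)),
    row = as.integer(rbind(scene$row, scene$row + !dh)),
    col = as.integer(rbind(scene$col, scene$col + dh))
  )
}

#' Compact scene code
#'
#' Serializes a scene as `"<pair_id><orientation>@<row>,<col>;..."` with
#' placements sorted by (row, col) so translation-identical scenes share a
#' code. [parse_scene_code()] inverts it.
#'
#' @param scene A scene tibble.
#' @param code A scene-code string.
#' @return A single string / a scene tibble.
#' @export
scene_code <- function(scene) {
  scene <- scene[order(scene$row, scene$col, scene$pair_id), ]
  paste(sprintf("%d%s@%d,%d", scene$pair_id, scene$orientation,
                scene$row, scene$col), collapse = ";")
}

#' @rdname scene_code
#' @export
parse_scene_code <- function(code) {
  parts <- strsplit(code, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(\\d+)([hv])@(\\d+),(\\d+)$", parts))
  stopifnot(all(lengths(m) == 5))
  new_scene(
    pair_id = vapply(m, function(x) as.integer(x[2]), integer(1)),
    orientation = vapply(m, function(x) x[3], character(1)),
    row = vapply(m, function(x) as.integer(x[4]), integer(1)),
    col = vapply(m, function(x) as.integer(x[5]), integer(1))
  )
}

#' Canonicalize a scene by translation
#'
#' Translates all placements so the bounding box touches row 0 and column 0.
#' Pair identities are untouched; the operation is idempotent, so two scenes
#' that differ only by a rigid translation share one canonical form.
#'
#' @param scene A scene tibble.
#' @return The translated scene tibble.
#' @export
canonicalize <- function(scene) {
  scene$row <- scene$row - min(scene$row)
  scene$col <- scene$col - min(scene$col)
  scene
}

#' Check a scene against the exposure-placement constraints
#'
#' Standalone validator for the three constraints that define the visual
#' exposure set on the `n × n` grid: (1) every pair has at least one cell
#' edge-adjacent (4-neighborhood) to a cell of another pair; (2) the centre
#' cell is occupied; (3) no two placements overlap and all cells lie on the
#' grid. Constraint (2) is evaluated on the coordinates as given, i.e. before
#' any canonicalization.
#'
#' @param scene A scene tibble.
#' @param n_rows,n_cols Grid size (default 3 x 3).
#' @return `TRUE`/`FALSE`.
#' @export
valid_exposure_scene <- function(scene, n_rows = 3, n_cols = 3) {
  cells <- scene_cells(scene)
  if (anyDuplicated(cells[, c("row", "col")]) > 0) return(FALSE)
  if (any(cells$row < 0 | cells$row >= n_rows |
          cells$col < 0 | cells$col >= n_cols)) return(FALSE)
  centre <- c((n_rows - 1L) %/% 2L, (n_cols - 1L) %/% 2L)
  if (!any(cells$row == centre[1] & cells$col == centre[2])) return(FALSE)
  # Pairwise 4-adjacency: each pair must touch some other pair edge-on.
  for (p in unique(cells$pair_id)) {
    mine <- cells[cells$pair_id == p, ]
    others <- cells[cells$pair_id != p, ]
    touch <- outer(mine$row, others$row, function(a, b) abs(a - b)) +
      outer(mine$col, others$col, function(a, b) abs(a - b))
    if (!any(touch == 1)) return(FALSE)
  }
  TRUE
}

#' Enumerate the visual-exposure scene set
#'
#' Exhaustively places 3 distinct true pairs of a 3-horizontal + 3-vertical
#' inventory on a 3 x 3 grid subject to the placement constraints (see
#' [valid_exposure_scene()]), deduplicating translation-equivalent
#' configurations. With the standard inventory this yields 444 unique scenes
#' in which each pair appears 222 times.
#'
#' @param inventory A `vhsl_inventory` with exactly 3 horizontal and 3
#'   vertical true pairs.
#' @return A tibble with one row per unique canonical scene: `scene_id`,
#'   `scene_code`, `category` (one of `3H`, `3V`, `2H1V_aligned`,
#'   `2H1V_offset`, `2V1H_aligned`, `2V1H_offset`), `pair_1`, `pair_2`,
#'   `pair_3` (sorted ids), and a `scene` list-column of placement tibbles.
#' @export
enumerate_exposure_scenes <- function(inventory) {
  tp <- inventory$pairs[inventory$pairs$kind == "true", ]
  if (inventory$n_true_h != 3 || inventory$n_true_v != 3) {
    stop("invalid inventory: exposure enumeration needs 3 horizontal and 3 ",
         "vertical true pairs.", call. = FALSE)
  }
  # Geometric placement slots on the 3x3 grid (cells indexed 3*row + col).
  slot_tab <- rbind(
    cbind(orient = 1L, expand.grid(row = 0:2, col = 0:1)),  # h: cells c, c+1
    cbind(orient = 2L, expand.grid(row = 0:1, col = 0:2))   # v: cells c, c+3
  )
  slot_cells <- t(apply(slot_tab, 1, function(s) {
    c0 <- 3L * s[["row"]] + s[["col"]]
    c(c0, c0 + if (s[["orient"]] == 1L) 1L else 3L)
  }))
  # 4-neighborhood adjacency between grid cells.
  rc <- cbind(row = (0:8) %/% 3L, col = (0:8) %% 3L)
  adj <- as.matrix(stats::dist(rc, method = "manhattan")) == 1
  n_slot <- nrow(slot_tab)
  overlap <- matrix(FALSE, n_slot, n_slot)
  touch <- matrix(FALSE, n_slot, n_slot)
  for (i in seq_len(n_slot)) for (j in seq_len(n_slot)) {
    overlap[i, j] <- any(slot_cells[i, ] %in% slot_cells[j, ])
    touch[i, j] <- any(adj[slot_cells[i, ] + 1L, slot_cells[j, ] + 1L])
  }
  slots_h <- which(slot_tab$orient == 1L)
  slots_v <- which(slot_tab$orient == 2L)

  combos <- utils::combn(tp$pair_id, 3, simplify = FALSE)
  seen <- new.env(parent = emptyenv())
  out <- vector("list", 2000L)
  n_out <- 0L
  centre_cell <- 4L
  for (ids in combos) {
    ors <- tp$orientation[match(ids, tp$pair_id)]
    s1 <- if (ors[1] == "h") slots_h else slots_v
    s2 <- if (ors[2] == "h") slots_h else slots_v
    s3 <- if (ors[3] == "h") slots_h else slots_v
    for (i in s1) for (j in s2) {
      if (overlap[i, j]) next
      for (k in s3) {
        if (overlap[i, k] || overlap[j, k]) next
        if (!any(c(slot_cells[i, ], slot_cells[j, ], slot_cells[k, ]) ==
                   centre_cell)) next
        tij <- touch[i, j]; tik <- touch[i, k]; tjk <- touch[j, k]
        if (!((tij || tik) && (tij || tjk) && (tik || tjk))) next
        sl <- c(i, j, k)
        rows <- slot_tab$row[sl]; cols <- slot_tab$col[sl]
        rows <- rows - min(rows); cols <- cols - min(cols)
        ord <- order(rows, cols, ids)
        code <- paste(ids[ord], ors[ord], rows[ord], cols[ord], collapse = ";")
        if (!is.null(seen[[code]])) next
        seen[[code]] <- TRUE
        n_out <- n_out + 1L
        out[[n_out]] <- new_scene(ids[ord], ors[ord], rows[ord], cols[ord])
      }
    }
  }
  scenes <- out[seq_len(n_out)]
  tibble::tibble(
    scene_id = seq_along(scenes),
    scene_code = vapply(scenes, scene_code, character(1)),
    category = vapply(scenes, classify_exposure_scene, character(1)),
    pair_1 = vapply(scenes, function(s) sort(s$pair_id)[1], integer(1)),
    pair_2 = vapply(scenes, function(s) sort(s$pair_id)[2], integer(1)),
    pair_3 = vapply(scenes, function(s) sort(s$pair_id)[3], integer(1)),
    scene = scenes
  )
}

# Category of a 3-pair exposure scene: orientation multiset, plus whether the
# two same-orientation pairs are mutually aligned (same columns for H pairs,
# same rows for V pairs).
classify_exposure_scene <- function(scene) {
  n_h <- sum(scene$orientation == "h")
  if (n_h == 3) return("3H")
  if (n_h == 0) return("3V")
  if (n_h == 2) {
    hh <- scene[scene$orientation == "h", ]
    if (hh$col[1] == hh$col[2]) "2H1V_aligned" else "2H1V_offset"
  } else {
    vv <- scene[scene$orientation == "v", ]
    if (vv$row[1] == vv$row[2]) "2V1H_aligned" else "2V1H_offset"
  }
}

#' Build a 2 x 2 scene from two same-orientation pairs
#'
#' Two horizontal pairs are stacked (the first argument of `order = "ab"`
#' occupies row 0); two vertical pairs sit side by side (`order = "ab"` puts
#' `pair_a` in column 0). The pairs touch on their long sides, forming a
#' 2 x 2 block.
#'
#' @param pair_a,pair_b Rows of an inventory pair table (or one-row tibbles)
#'   with `pair_id` and `orientation`; orientations must match and the pairs
#'   must be distinct.
#' @param order `"ab"` or `"ba"`: which pair takes the top row (horizontal) or
#'   the left column (vertical).
#' @return A scene tibble.
#' @export
make_2x2_scene <- function(pair_a, pair_b, order = c("ab", "ba")) {
  order <- match.arg(order)
  if (pair_a$orientation != pair_b$orientation) {
    stop("invalid scene: a 2x2 block needs two pairs of the same orientation.",
         call. = FALSE)
  }
  if (pair_a$pair_id == pair_b$pair_id) {
    stop("invalid scene: the two pairs must be distinct.", call. = FALSE)
  }
  if (order == "ba") { tmp <- pair_a; pair_a <- pair_b; pair_b <- tmp }
  if (pair_a$orientation == "h") {
    new_scene(c(pair_a$pair_id, pair_b$pair_id), c("h", "h"), c(0L, 1L), c(0L, 0L))
  } else {
    new_scene(c(pair_a$pair_id, pair_b$pair_id), c("v", "v"), c(0L, 0L), c(0L, 1L))
  }
}
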