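#' Build a shape-pair inventory
#'
#' Constructs the inventory used throughout a two-modality statistical-learning
#' experiment: `n_true_h` horizontal and `n_true_v` vertical *true pairs* (the
#' "objects", each owning two shapes that always co-occur in a fixed spatial
#' arrangement) plus an equal number of chimeric *pseudo pairs*. Each horizontal
#' pseudo pair takes the top shape of one vertical true pair and the bottom
#' shape of a different vertical true pair (and symmetrically, vertical pseudo
#' pairs re-use left/right shapes of two different horizontal true pairs), so
#' pseudo pairs exactly repartition the shape set: every shape belongs to one
#' true pair and one pseudo pair.
#'
#' Donor true pairs are matched cyclically after a seeded permutation: donor
#' `i` contributes its top/left shape and donor `i + 1` (mod n) its
#' bottom/right shape. This guarantees the two shapes of a pseudo pair come
#' from two different true pairs whenever at least two donors exist.
#'
#' @param n_true_h,n_true_v Number of horizontal / vertical true pairs; both
#'   must be at least 2 (a pseudo pair needs two distinct donors).
#' @param seed Integer seed driving the shape-to-pair assignment; required.
#' @return An object of class `vhsl_inventory`: a list with `pairs` (a tibble
#'   with one row per pair: `pair_id`, `kind` ("true"/"pseudo"), `orientation`
#'   ("h"/"v"), `first`, `second` shape ids; `first` is the left cell for
#'   horizontal and the top cell for vertical pairs), and counts
#'   `n_true_h`, `n_true_v`, `n_shapes`, plus the `seed`.
#' @examples
#' inv <- build_inventory(3, 3, seed = 1)
#' inv$n_shapes # 12
#' @export
build_inventory <- function(n_true_h, n_true_v, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required: inventory randomization must be reproducible.",
         call. = FALSE)
  }
  if (n_true_h < 2 || n_true_v < 2) {
    stop("invalid inventory: need at least 2 true pairs per orientation ",
         "(pseudo pairs require two distinct donor pairs).", call. = FALSE)
  }
  n_true <- n_true_h + n_true_v
  n_shapes <- 2L * n_true

  rng <- local_rng(seed)
  shape_perm <- rng_sample(rng, seq_len(n_shapes)) - 1L  # 0-based shape ids

  # True pairs: consecutive shapes from the permuted pool, horizontals first.
  first <- shape_perm[seq(1L, n_shapes, by = 2L)]
  second <- shape_perm[seq(2L, n_shapes, by = 2L)]
  true_pairs <- tibble::tibble(
    pair_id = seq_len(n_true),
    kind = "true",
    orientation = rep(c("h", "v"), c(n_true_h, n_true_v)),
    first = first,
    second = second
  )

  # Pseudo pairs: horizontal pseudos repartition the vertical true pairs'
  # shapes (one top + one bottom shape from two different donors), and
  # vice versa. Donor order is seed-permuted, matching is cyclic.
  pseudo_from <- function(donors, orientation_out) {
    ord <- rng_sample(rng, seq_len(nrow(donors)))
    donors <- donors[ord, ]
    n <- nrow(donors)
    tibble::tibble(
      kind = "pseudo",
      orientation = orientation_out,
      first = donors$first,                      # top (or left) shape of donor i
      second = donors$second[c(seq_len(n)[-1L], 1L)]  # bottom/right of donor i+1
    )
  }
  pseudo <- dplyr::bind_rows(
    pseudo_from(true_pairs[true_pairs$orientation == "v", ], "h"),
    pseudo_from(true_pairs[true_pairs$orientation == "h", ], "v")
  )
  pseudo$pair_id <- n_true + seq_len(nrow(pseudo))
  pairs <- dplyr::bind_rows(true_pairs, pseudo[, names(true_pairs)])

  inv <- structure(
    list(pairs = pairs, n_true_h = as.integer(n_true_h),
         n_true_v = as.integer(n_true_v), n_shapes = as.integer(n_shapes),
         seed = as.integer(seed)),
    class = "vhsl_inventory"
  )
  validate_inventory(inv)
  inv
}

#' Validate inventory invariants
#'
#' Checks the structural invariants of an inventory: unique contiguous shape
#' ids, every shape in exactly one true and one pseudo pair, pseudo pairs never
#' reproducing a true pair's shape set, and the donor-role rule (a horizontal
#' pseudo pair uses the top shape of one vertical true pair and the bottom
#' shape of a different one; symmetrically for vertical pseudos).
#'
#' @param inv A `vhsl_inventory`.
#' @return `inv`, invisibly; errors if any invariant fails.
#' @export
validate_inventory <- function(inv) {
  p <- inv$pairs
  tp <- p[p$kind == "true", ]
  pp <- p[p$kind == "pseudo", ]
  shapes_true <- sort(c(tp$first, tp$second))
  shapes_pseudo <- sort(c(pp$first, pp$second))
  stopifnot(
    identical(shapes_true, shapes_pseudo),
    identical(shapes_true, 0:(inv$n_shapes - 1L)),
    all(p$first != p$second),
    nrow(tp) == nrow(pp),
    sum(tp$orientation == "h") == inv$n_true_h,
    sum(pp$orientation == "h") == inv$n_true_v  # orientations swapped
  )
  # No pseudo pair equals a true pair as a shape set.
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  if (any(key(pp$first, pp$second) %in% key(tp$first, tp$second))) {
    stop("invalid inventory: a pseudo pair duplicates a true pair.", call. = FALSE)
  }
  # Donor-role rule.
  donor_of <- function(shape, role) tp$pair_id[tp[[role]] == shape]
  for (i in seq_len(nrow(pp))) {
    d1 <- donor_of(pp$first[i], "first")
    d2 <- donor_of(pp$second[i], "second")
    want <- if (pp$orientation[i] == "h") "v" else "h"
    ok <- length(d1) == 1 && length(d2) == 1 && d1 != d2 &&
      all(tp$orientation[tp$pair_id %in% c(d1, d2)] == want)
    if (!ok) stop("invalid inventory: pseudo pair violates the donor-role rule.",
                  call. = FALSE)
  }
  invisible(inv)
}

#' Tabulate inventory pairs
#'
#' @param x A `vhsl_inventory`.
#' @param ... Unused.
#' @return The pair table as a tibble.
#' @method tidy vhsl_inventory
#' @export
tidy.vhsl_inventory <- function(x, ...) x$pairs

#' @export
print.vhsl_inventory <- function(x, ...) {
  cat(sprintf("<vhsl_inventory> %d shapes, %d+%d true pairs (h+v), seed %d\n",
              x$n_shapes, x$n_true_h, x$n_true_v, x$seed))
  print(x$pairs, n = nrow(x$pairs))
  invisible(x)
}

#' Write / read an inventory as JSON
#'
#' @param inv A `vhsl_inventory`.
#' @param path File path.
#' @return `write_inventory_json()` returns `path` invisibly;
#'   `read_inventory_json()` returns the reconstructed `vhsl_inventory`.
#' @export
write_inventory_json <- function(inv, path) {
  obj <- list(
    n_true_h = inv$n_true_h, n_true_v = inv$n_true_v,
    n_shapes = inv$n_shapes, seed = inv$seed,
    pairs = inv$pairs
  )
  atomic_write(path, function(tmp) {
    jsonlite::write_json(obj, tmp, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  })
  invisible(path)
}

#' @rdname write_inventory_json
#' @export
read_inventory_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  inv <- structure(
    list(pairs = tibble::as_tibble(obj$pairs),
         n_true_h = as.integer(obj$n_true_h),
         n_true_v = as.integer(obj$n_true_v),
         n_shapes = as.integer(obj$n_shapes),
         seed = as.integer(obj$seed)),
    class = "vhsl_inventory"
  )
  validate_inventory(inv)
  inv
}

#' Swap two shapes between two same-orientation true pairs
#'
#' Produces the "internalized wrong inventory" used by the cohort simulator:
#' the second shapes of two distinct same-orientation true pairs are exchanged,
#' so a participant holding this inventory treats two chimeric pairs as the
#' objects. All structural fields are preserved.
#'
#' @param inv A `vhsl_inventory`.
#' @param pair_a,pair_b `pair_id`s of two distinct true pairs with the same
#'   orientation.
#' @return A new `vhsl_inventory` (not re-validated: the swap intentionally
#'   breaks the pseudo-pair donor bookkeeping relative to the new true pairs).
#' @export
swap_true_pairs <- function(inv, pair_a, pair_b) {
  p <- inv$pairs
  ia <- which(p$pair_id == pair_a & p$kind == "true")
  ib <- which(p$pair_id == pair_b & p$kind == "true")
  stopifnot(length(ia) == 1, length(ib) == 1,
            p$orientation[ia] == p$orientation[ib], ia != ib)
  tmp <- p$second[ia]
  p$second[ia] <- p$second[ib]
  p$second[ib] <- tmp
  out <- inv
  out$pairs <- p
  out
}
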