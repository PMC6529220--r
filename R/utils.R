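#' @importFrom generics tidy glance augment
#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
#' @importFrom stats rnorm runif rbinom rbeta optim qchisq pchisq pt qt
#'   cor cor.test t.test integrate sd lm resid coef dbinom var quantile
#' @importFrom utils head
NULL

# Self-contained RNG stream: every stochastic routine in the package draws
# from an explicit stream created from an integer seed, so the caller's
# .Random.seed is never consumed or clobbered and two calls with the same
# seed are identical regardless of ambient RNG state.
local_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- new.env(parent = emptyenv())
  rng_scope(NULL, env, function() set.seed(as.integer(seed)))
  env
}

# Run fn() with the stream's state installed, then capture the advanced state.
rng_scope <- function(state, rng, fn) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
  on.exit({
    rng$state <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  fn()
}

rng_eval <- function(rng, fn) rng_scope(rng$state, rng, fn)

rng_sample <- function(rng, x, size = length(x), replace = FALSE) {
  rng_eval(rng, function() sample(x, size = size, replace = replace))
}
rng_runif <- function(rng, n, min = 0, max = 1) {
  rng_eval(rng, function() runif(n, min, max))
}
rng_rnorm <- function(rng, n, mean = 0, sd = 1) {
  rng_eval(rng, function() rnorm(n, mean, sd))
}
rng_rbinom <- function(rng, n, size, prob) {
  rng_eval(rng, function() rbinom(n, size, prob))
}
rng_rbeta <- function(rng, n, a, b) {
  rng_eval(rng, function() rbeta(n, a, b))
}
# Derive a fresh child seed from a stream (for nested reproducible stages).
rng_child_seed <- function(rng) {
  rng_eval(rng, function() sample.int(.Machine$integer.max, 1L))
}

# Write-then-rename so interrupted runs never leave truncated files.
atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp-", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
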