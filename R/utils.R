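# Internal helpers: seeded RNG scoping and seed derivation.

#' Evaluate an expression under a local RNG seed
#'
#' Restores the caller's RNG state afterwards, so library code never leaks
#' randomness into (or consumes randomness from) the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed and a label
#'
#' Stable string hash (polynomial rolling, modulo a Mersenne prime) combined
#' with the master seed, so that pipeline stages can be rerun independently
#' yet reproducibly. Always returns a value in [0, 2^31 - 2].
#' @noRd
derive_seed <- function(seed, tag) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assert that a value is a single finite number
#' @noRd
check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}
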