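# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  All stochastic package operations go
# through this so that a (config, seed) pair pins the result exactly.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Half-up decimal rounding (base round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic k-fold assignment: a seeded permutation of systematically
# interleaved fold labels.  Returns an integer vector of fold ids in 1..k.
make_folds <- function(n, k, seed = NULL) {
  k <- min(k, n)
  ids <- rep_len(seq_len(k), n)
  if (!is.null(seed)) ids <- with_seed(seed, sample(ids))
  as.integer(ids)
}

as_matrix_x <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop_invalid("X must be a numeric matrix (samples x variables)")
  }
  X
}
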