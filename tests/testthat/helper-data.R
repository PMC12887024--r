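# Fixture builders; everything is generated in code under fixed seeds.

tiny_config <- function(seed = 7, ...) {
  generator_config(n_per_market = 4, n_points = 128, seed = seed, ...)
}

tiny_dataset <- function(seed = 7, ...) simulate_dataset(tiny_config(seed, ...))

# Selector benchmark: first column carries the signal, the rest are noise.
informative_matrix <- function(n = 60, p = 20, seed = 42, noise = 0) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    y <- X[, 1] + if (noise > 0) rnorm(n, sd = noise) else 0
    list(X = X, y = y)
  })
}
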