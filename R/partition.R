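#' Kennard--Stone sample selection
#'
#' Deterministic maximin-distance design: start from the most distant pair,
#' then repeatedly add the sample whose minimum Euclidean distance to the
#' already-selected set is largest.  Ties break to the lowest row index.
#'
#' @param X Numeric matrix, samples x variables.
#' @param k Number of samples to select (>= 2).
#' @return Integer vector of selected row indices, in selection order.
#' @export
kennard_stone <- function(X, k) {
  X <- as_matrix_x(X)
  n <- nrow(X)
  if (k < 2 || k > n) stop_invalid("k must lie in [2, %d]", n)
  D <- as.matrix(stats::dist(X))
  # most distant pair, ties -> lowest indices
  far <- which(D == max(D), arr.ind = TRUE)
  far <- far[order(far[, 1], far[, 2]), , drop = FALSE][1, ]
  sel <- sort(c(far[1], far[2]))
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < k) {
    mind[sel] <- -Inf
    nxt <- which.max(mind)   # which.max takes the first maximum: lowest index
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  as.integer(sel)
}

#' Partition samples into calibration and prediction sets
#'
#' Splits `n` samples at `ratio_cal : ratio_pred` with
#' `n_cal = floor(n * ratio_cal / (ratio_cal + ratio_pred))` -- the default
#' 2:1 split of 200 samples yields 133 calibration and 67 prediction
#' samples.  The default method is Kennard--Stone on the raw spectra
#' (deterministic; rows are canonically ordered by sample id first so the
#' result is invariant to input row order); `"random"` draws a seeded
#' random split.
#'
#' @param x A `spectral_dataset`, a numeric matrix, or an integer sample
#'   count (random method only).
#' @param ratio_cal,ratio_pred Split ratio (default 2:1).
#' @param method `"kennard_stone"` or `"random"`.
#' @param seed Seed for the random method.
#' @return List of class `partition` with sorted integer index vectors
#'   `calibration` and `prediction`.
#' @export
partition_samples <- function(x, ratio_cal = 2, ratio_pred = 1,
                              method = c("kennard_stone", "random"), seed = 1) {
  method <- match.arg(method)
  ids <- NULL
  if (inherits(x, "spectral_dataset")) {
    ids <- x$meta$sample_id
    X <- x$intensities
    n <- nrow(X)
  } else if (is.matrix(x)) {
    X <- x
    n <- nrow(X)
  } else {
    n <- as.integer(x)
    X <- NULL
    if (method == "kennard_stone") {
      stop_invalid("kennard_stone needs spectra; pass a dataset or matrix")
    }
  }
  if (n < 3) stop_invalid("need at least 3 samples to partition (got %d)", n)
  n_cal <- floor(n * ratio_cal / (ratio_cal + ratio_pred))
  cal <- if (method == "random") {
    with_seed(seed, sort(sample.int(n, n_cal)))
  } else {
    ord <- if (!is.null(ids)) order(ids) else seq_len(n)
    sel <- kennard_stone(X[ord, , drop = FALSE], n_cal)
    sort(ord[sel])
  }
  structure(list(calibration = cal,
                 prediction = setdiff(seq_len(n), cal),
                 method = method, seed = seed, n = n),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("Partition (%s): %d calibration / %d prediction of %d samples\n",
              x$method, length(x$calibration), length(x$prediction), x$n))
  invisible(x)
}
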