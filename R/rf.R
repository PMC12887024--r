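#' Fit a random-forest calibration
#'
#' Ensemble of regression trees grown on bootstrap samples with random
#' feature subsetting at each split (`mtry = max(1, floor(p/3))`, the
#' regression convention); the prediction is the mean over trees.  Defaults
#' follow the study configuration this package mirrors: 250 trees and a
#' minimum leaf size of 10.  Deterministic for a given `seed`.
#'
#' @param X,y Calibration data.
#' @param n_trees Number of trees (>= 1).
#' @param min_leaf Minimum terminal-node size.
#' @param mtry Variables tried per split.
#' @param seed Integer seed.
#' @return Object of class `c("palm_rf", "palm_model")`; `oob_mse` holds
#'   the out-of-bag mean squared error trace over tree counts.
#' @export
fit_rf <- function(X, y, n_trees = 250, min_leaf = 10,
                   mtry = max(1, floor(ncol(X) / 3)), seed = 1) {
  X <- as_matrix_x(X)
  if (n_trees < 1) stop_invalid("n_trees must be >= 1")
  if (length(y) != nrow(X)) stop_invalid("length(y) != nrow(X)")
  # a leaf bound at or above n means a single-leaf (constant) tree; the
  # underlying implementation would still attempt one split, so force it
  maxnodes <- if (min_leaf >= nrow(X)) 1 else NULL
  rf <- with_seed(seed, randomForest::randomForest(
    x = X, y = y, ntree = n_trees, nodesize = min_leaf, mtry = mtry,
    maxnodes = maxnodes
  ))
  fitted <- as.numeric(stats::predict(rf, X))
  structure(
    list(rf = rf, n_trees = n_trees, min_leaf = min_leaf, mtry = mtry,
         seed = seed, n_variables = ncol(X), oob_mse = rf$mse,
         fitted_values = fitted, residuals = y - fitted,
         y = y, algorithm = "RF"),
    class = c("palm_rf", "palm_model")
  )
}

#' @export
predict.palm_rf <- function(object, newdata, ...) {
  newdata <- check_newdata(object, newdata)
  colnames(newdata) <- rownames(object$rf$importance)
  as.numeric(stats::predict(object$rf, newdata))
}
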