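#' Fit a partial least squares calibration (SIMPLS)
#'
#' Mean-centered SIMPLS fit for a single response.  Spectra are not
#' autoscaled: channels share intensity units and autoscaling would inflate
#' noise channels.  Prediction is the linear map
#' `yhat = (X - x_means) %*% b + y_mean`.
#'
#' @param X Numeric matrix, samples x variables.
#' @param y Numeric response (reference values).
#' @param ncomp Number of latent variables, `1 <= ncomp <= min(n - 1, p)`.
#' @return Object of class `c("palm_pls", "palm_model")` with elements
#'   `coefficients` (length-p vector for the `ncomp`-component model),
#'   `coef_path` (p x ncomp matrix, one column per component count),
#'   `x_means`, `y_mean`, `ncomp`, `fitted_values`, `residuals`.
#' @examples
#' X <- matrix(rnorm(60), 20, 3)
#' y <- 2 * X[, 1] + rnorm(20, sd = 0.01)
#' m <- fit_pls(X, y, ncomp = 1)
#' cor(predict(m, X), y)
#' @export
fit_pls <- function(X, y, ncomp) {
  X <- as_matrix_x(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_invalid("length(y) (%d) != nrow(X) (%d)", length(y), n)
  if (ncomp < 1 || ncomp > min(n - 1, p)) {
    stop_invalid("ncomp must lie in [1, %d] (got %d)", min(n - 1, p), ncomp)
  }
  if (stats::var(y) == 0) {
    warning("response has zero variance; model predicts the constant mean",
            call. = FALSE)
  }
  fit <- simpls_fit_cpp(X, y, as.integer(ncomp))
  b <- fit$coefficients[, ncomp]
  fitted <- as.numeric(sweep(X, 2, as.numeric(fit$x_means)) %*% b) + fit$y_mean
  structure(
    list(coefficients = b, coef_path = fit$coefficients,
         x_means = as.numeric(fit$x_means), y_mean = fit$y_mean,
         ncomp = ncomp, ncomp_used = fit$ncomp_used,
         n_variables = p, fitted_values = fitted, residuals = y - fitted,
         y = y, algorithm = "PLS"),
    class = c("palm_pls", "palm_model")
  )
}

#' @export
predict.palm_pls <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- check_newdata(object, newdata)
  b <- object$coef_path[, ncomp]
  as.numeric(sweep(newdata, 2, object$x_means) %*% b) + object$y_mean
}

#' @export
coef.palm_pls <- function(object, ...) object$coefficients

#' Cross-validated RMSE of PLS over component counts
#'
#' One SIMPLS fit per fold yields predictions for every component count
#' `1..max_components` simultaneously; RMSECV is pooled over folds.
#'
#' @param X,y Calibration data.
#' @param max_components Largest component count to evaluate.
#' @param cv_folds Number of folds.
#' @param fold_id Optional explicit fold assignment (1-based integers);
#'   defaults to a deterministic interleaved assignment.
#' @return Numeric vector of RMSECV values, one per component count.
#' @export
pls_cv_rmse <- function(X, y, max_components = 10, cv_folds = 5, fold_id = NULL) {
  X <- as_matrix_x(X)
  n <- nrow(X)
  kmax <- max(1L, min(max_components, ncol(X), n - ceiling(n / max(cv_folds, 2)) - 1L))
  if (is.null(fold_id)) fold_id <- make_folds(n, cv_folds)
  as.numeric(simpls_cv_rmse_cpp(X, y, as.integer(kmax), as.integer(fold_id)))
}

#' Choose the PLS component count by cross-validation
#'
#' Returns the component count with minimal cross-validated RMSE; ties go
#' to the smallest count.
#'
#' @inheritParams pls_cv_rmse
#' @return Integer component count.
#' @export
choose_pls_components <- function(X, y, max_components = 10, cv_folds = 5,
                                  fold_id = NULL) {
  if (max_components < 1) stop_invalid("max_components must be >= 1")
  rmse <- pls_cv_rmse(X, y, max_components, cv_folds, fold_id)
  which.min(rmse)
}
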