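# Common S3 surface of the calibration models.

check_newdata <- function(object, newdata) {
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$n_variables) {
    stop_invalid("newdata has %d variables but the model was trained on %d",
                 ncol(newdata), object$n_variables)
  }
  newdata
}

#' Fit a calibration model by algorithm name
#'
#' Front door over [fit_pls()], [fit_svr()] and [fit_rf()]; `...` passes
#' algorithm-specific hyperparameters through.
#'
#' @param X,y Calibration data.
#' @param algorithm `"pls"`, `"svm"` or `"rf"`.
#' @param ... Hyperparameters of the chosen fitter.
#' @return A `palm_model`.
#' @export
oil_model <- function(X, y, algorithm = c("pls", "svm", "rf"), ...) {
  switch(match.arg(algorithm),
         pls = fit_pls(X, y, ...),
         svm = fit_svr(X, y, ...),
         rf = fit_rf(X, y, ...))
}

#' @export
print.palm_model <- function(x, ...) {
  extra <- switch(x$algorithm,
    PLS = sprintf("%d latent variables", x$ncomp),
    SVM = sprintf("C = %.6g, gamma = %.6g, epsilon = %.3g%s", x$C, x$gamma,
                  x$epsilon,
                  if (!is.null(x$pca)) sprintf(", %d PCA components", x$pca$k) else ""),
    RF = sprintf("%d trees, min leaf %d, mtry %d", x$n_trees, x$min_leaf, x$mtry))
  cat(sprintf("%s calibration on %d variables (%s)\n",
              x$algorithm, x$n_variables, extra))
  cat(sprintf("  training RMSE %.4g over %d samples\n",
              sqrt(mean(x$residuals^2)), length(x$residuals)))
  invisible(x)
}

#' @export
summary.palm_model <- function(object, ...) {
  res <- object$residuals
  out <- list(algorithm = object$algorithm,
              n = length(res), n_variables = object$n_variables,
              rmsec = sqrt(mean(res^2)),
              rc = if (stats::sd(object$fitted_values) > 0)
                stats::cor(object$y, object$fitted_values) else NA_real_)
  class(out) <- "summary.palm_model"
  out
}

#' @export
print.summary.palm_model <- function(x, ...) {
  cat(sprintf("%s calibration: n = %d, p = %d, Rc = %.4f, RMSEC = %.4f\n",
              x$algorithm, x$n, x$n_variables, x$rc, x$rmsec))
  invisible(x)
}

#' @export
fitted.palm_model <- function(object, ...) object$fitted_values

#' @export
residuals.palm_model <- function(object, ...) object$residuals
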