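#' Pearson correlation between reference and predicted values
#'
#' The calibration/prediction correlation coefficients (Rc, Rp) of the
#' evaluation suite.  Errors on constant input rather than returning NA.
#'
#' @param y,yhat Equal-length numeric vectors (length >= 2).
#' @return Pearson correlation in \[-1, 1\].
#' @export
pearson_r <- function(y, yhat) {
  if (length(y) != length(yhat)) stop_invalid("length mismatch: %d vs %d",
                                              length(y), length(yhat))
  if (length(y) < 2) stop_invalid("need at least 2 observations")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    stop_invalid("correlation undefined for constant input")
  }
  stats::cor(y, yhat)
}

#' Root mean square error
#' @param y,yhat Equal-length numeric vectors.
#' @return `sqrt(mean((y - yhat)^2))`, in reference units.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop_invalid("length mismatch: %d vs %d",
                                              length(y), length(yhat))
  sqrt(mean((y - yhat)^2))
}

#' Residual predictive deviation
#'
#' Sample standard deviation (n-1 denominator) of the prediction-set
#' reference values divided by RMSEP.
#'
#' @param y_ref Prediction-set reference values (non-constant).
#' @param rmsep Root mean square error of prediction (> 0).
#' @return RPD, unitless.
#' @export
rpd <- function(y_ref, rmsep) {
  s <- stats::sd(y_ref)
  if (!is.finite(s) || s == 0) stop_invalid("RPD undefined: constant reference values")
  if (rmsep == 0) stop_invalid("RPD infinite: rmsep is 0")
  if (rmsep < 0) stop_invalid("rmsep must be > 0")
  s / rmsep
}

#' Classify an RPD value
#'
#' RPD >= 3 indicates excellent model reliability, values in \[2, 3) are
#' acceptable, and values below 2 signal limited predictive ability.
#'
#' @param x RPD value (> 0).
#' @return `"excellent"`, `"acceptable"` or `"limited"`.
#' @export
classify_rpd <- function(x) {
  if (any(x <= 0)) stop_invalid("RPD must be > 0")
  ifelse(x >= 3, "excellent", ifelse(x >= 2, "acceptable", "limited"))
}

#' Evaluate a fitted calibration model on a partition
#'
#' Computes Rc/RMSEC on the calibration samples and Rp/RMSEP/RPD on the
#' prediction samples of `dataset`, restricted to the selected variables
#' the model was trained on.
#'
#' @param model A fitted `palm_model` (trained on
#'   `dataset$intensities[partition$calibration, selected]`).
#' @param partition A [partition_samples()] result.
#' @param dataset The (preprocessed) `spectral_dataset`.
#' @param parameter `"pv"` or `"iv"`.
#' @param selected Variable indices the model uses (default: all).
#' @param model_name Label for the report row.
#' @return List of class `evaluation_report` with fields `Rc`, `RMSEC`,
#'   `Rp`, `RMSEP`, `RPD`, `rpd_class`, `n_cal`, `n_pred`, `n_variables`,
#'   `n_components`, and the per-sample `predictions`.
#' @export
evaluate_model <- function(model, partition, dataset,
                           parameter = c("pv", "iv"),
                           selected = NULL, model_name = model$algorithm) {
  parameter <- match.arg(parameter)
  y <- dataset$meta[[parameter]]
  X <- dataset$intensities
  if (is.null(selected)) selected <- seq_len(ncol(X))
  Xs <- X[, selected, drop = FALSE]
  cal <- partition$calibration; pred <- partition$prediction
  yc_hat <- predict(model, Xs[cal, , drop = FALSE])
  yp_hat <- predict(model, Xs[pred, , drop = FALSE])
  rmsec <- rmse(y[cal], yc_hat)
  rmsep <- rmse(y[pred], yp_hat)
  rpd_val <- rpd(y[pred], rmsep)
  structure(
    list(parameter = toupper(parameter), model = model_name,
         Rc = pearson_r(y[cal], yc_hat), RMSEC = rmsec,
         Rp = pearson_r(y[pred], yp_hat), RMSEP = rmsep,
         RPD = rpd_val, rpd_class = classify_rpd(rpd_val),
         n_cal = length(cal), n_pred = length(pred),
         n_variables = length(selected),
         n_components = model$ncomp %||% NA_integer_,
         predictions = data.frame(
           sample_id = dataset$meta$sample_id[c(cal, pred)],
           set = rep(c("calibration", "prediction"), c(length(cal), length(pred))),
           reference = c(y[cal], y[pred]),
           predicted = c(yc_hat, yp_hat))),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "%s / %s: Rc = %.4f RMSEC = %.4f | Rp = %.4f RMSEP = %.4f | RPD = %.4f (%s)\n",
    x$parameter, x$model, x$Rc, x$RMSEC, x$Rp, x$RMSEP, x$RPD, x$rpd_class))
  invisible(x)
}

#' Flatten evaluation reports to a table row
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return One-row data frame in the experiment-table column order.
#' @export
as.data.frame.evaluation_report <- function(x, ...) {
  data.frame(parameter = x$parameter, model = x$model,
             PCs = x$n_components, n_variables = x$n_variables,
             Rc = x$Rc, RMSEC = x$RMSEC, Rp = x$Rp, RMSEP = x$RMSEP,
             RPD = x$RPD, rpd_class = x$rpd_class,
             stringsAsFactors = FALSE)
}
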