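#' Fit an epsilon-SVR calibration with RBF kernel
#'
#' Pipeline: per-variable linear scaling of the training spectra to
#' `[-1, 1]`, PCA retaining the smallest number of components whose
#' cumulative variance reaches `pca_variance`, then
#' \eqn{\varepsilon}-support-vector regression with a radial basis kernel
#' (LIBSVM via \pkg{e1071}).  The response is standardized internally, so
#' `epsilon` is in units of response SDs.  All training-derived transforms
#' (scaling ranges, PCA loadings, response moments) are frozen at fit time
#' and applied to prediction inputs.
#'
#' @param X,y Calibration data.
#' @param C Penalty parameter (> 0).
#' @param gamma RBF kernel width (> 0); default `1/ncol(X)`.
#' @param epsilon Insensitive-tube half-width after response
#'   standardization.
#' @param pca_variance Fraction of spectral variance retained by the PCA
#'   step (0 disables PCA).
#' @param scale_range Target range of the per-variable scaling; `NULL`
#'   disables scaling.
#' @param ... Further arguments to [e1071::svm()] (e.g. `tolerance`).
#' @return Object of class `c("palm_svr", "palm_model")`.
#' @export
fit_svr <- function(X, y, C = 1, gamma = NULL, epsilon = 0.1,
                    pca_variance = 0.95, scale_range = c(-1, 1), ...) {
  X <- as_matrix_x(X)
  if (C <= 0 || epsilon < 0) stop_invalid("C must be > 0 and epsilon >= 0")
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_invalid("length(y) (%d) != nrow(X) (%d)", length(y), n)

  scaling <- NULL
  Z <- X
  if (!is.null(scale_range)) {
    lo <- apply(X, 2, min); hi <- apply(X, 2, max)
    flat <- hi == lo
    if (any(flat)) {
      warning(sprintf("%d zero-variance variable(s) mapped to 0 by scaling",
                      sum(flat)), call. = FALSE)
    }
    span <- ifelse(flat, 1, hi - lo)
    scaling <- list(lo = lo, span = span, flat = flat, range = scale_range)
    Z <- scale_to_range(X, scaling)
  }

  pca <- NULL
  if (!is.null(pca_variance) && pca_variance > 0 && p > 1) {
    pc <- stats::prcomp(Z, center = TRUE, scale. = FALSE)
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    k <- which(cum >= pca_variance)[1]
    if (is.na(k)) k <- length(pc$sdev)
    pca <- list(center = pc$center, rotation = pc$rotation[, seq_len(k), drop = FALSE],
                k = k, cum_variance = cum[k])
    Z <- pc$x[, seq_len(k), drop = FALSE]
  }

  y_center <- mean(y); y_scale <- stats::sd(y)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  ys <- (y - y_center) / y_scale
  if (is.null(gamma)) gamma <- 1 / ncol(Z)
  if (gamma <= 0) stop_invalid("gamma must be > 0")
  # constant response: every point sits inside the epsilon tube of the
  # flat function, so the dual is empty; short-circuit to that solution
  svm_fit <- if (stats::sd(ys) == 0) NULL else
    e1071::svm(x = Z, y = ys, type = "eps-regression",
               kernel = "radial", cost = C, gamma = gamma,
               epsilon = epsilon, scale = FALSE, ...)
  obj <- structure(
    list(svm = svm_fit, scaling = scaling, pca = pca,
         y_center = y_center, y_scale = y_scale,
         C = C, gamma = gamma, epsilon = epsilon,
         n_variables = p, y = y, algorithm = "SVM"),
    class = c("palm_svr", "palm_model")
  )
  obj$fitted_values <- predict(obj, X)
  obj$residuals <- y - obj$fitted_values
  obj
}

scale_to_range <- function(X, scaling) {
  lo2 <- scaling$range[1]; span2 <- scaling$range[2] - scaling$range[1]
  Z <- sweep(sweep(X, 2, scaling$lo), 2, scaling$span, "/") * span2 + lo2
  if (any(scaling$flat)) Z[, scaling$flat] <- 0
  Z
}

#' @export
predict.palm_svr <- function(object, newdata, ...) {
  newdata <- check_newdata(object, newdata)
  Z <- newdata
  if (!is.null(object$scaling)) Z <- scale_to_range(Z, object$scaling)
  if (!is.null(object$pca)) {
    Z <- sweep(Z, 2, object$pca$center) %*% object$pca$rotation
  }
  ys <- if (is.null(object$svm)) rep(0, nrow(Z)) else
    as.numeric(stats::predict(object$svm, Z))
  ys * object$y_scale + object$y_center
}

#' Grid search for SVR hyperparameters
#'
#' Exhaustive cross-validation over a log2-spaced (C, gamma) grid, followed
#' by one local refinement pass (a factor-2 bracket around the coarse
#' optimum, 5 points per axis) so that optima between powers of two are
#' expressible.  Ties break to the smallest C, then the smallest gamma.
#'
#' @param X,y Calibration data.
#' @param C_grid,gamma_grid Candidate values; defaults
#'   \eqn{2^{-4}..2^{10}} and \eqn{2^{-10}..2^{4}}.
#' @param cv_folds Number of CV folds.
#' @param epsilon,pca_variance,scale_range Passed to [fit_svr()].
#' @param refine Run the local refinement pass.
#' @param fold_id Optional explicit fold assignment.
#' @return List with `C`, `gamma`, `rmsecv` (at the optimum) and `surface`
#'   (data frame `C`, `gamma`, `rmsecv`, `stage`) -- the data behind a 3D
#'   hyperparameter response surface.
#' @export
grid_search_svr <- function(X, y, C_grid = 2^seq(-4, 10), gamma_grid = 2^seq(-10, 4),
                            cv_folds = 5, epsilon = 0.1, pca_variance = 0.95,
                            scale_range = c(-1, 1), refine = TRUE, fold_id = NULL) {
  X <- as_matrix_x(X)
  if (!length(C_grid) || !length(gamma_grid)) stop_invalid("empty hyperparameter grid")
  n <- nrow(X)
  if (is.null(fold_id)) fold_id <- make_folds(n, cv_folds)

  eval_grid <- function(Cs, gs, stage) {
    cells <- expand.grid(C = sort(Cs), gamma = sort(gs))
    cells$rmsecv <- vapply(seq_len(nrow(cells)), function(i) {
      svr_cv_rmse(X, y, cells$C[i], cells$gamma[i], epsilon,
                  pca_variance, scale_range, fold_id)
    }, numeric(1))
    cells$stage <- stage
    cells
  }
  surface <- eval_grid(C_grid, gamma_grid, "coarse")
  best <- surface[order(surface$rmsecv, surface$C, surface$gamma), ][1, ]
  if (refine && (length(C_grid) > 1 || length(gamma_grid) > 1)) {
    Cs <- best$C * 2^seq(-1, 1, length.out = 5)
    gs <- best$gamma * 2^seq(-1, 1, length.out = 5)
    surface <- rbind(surface, eval_grid(Cs, gs, "refine"))
    best <- surface[order(surface$rmsecv, surface$C, surface$gamma), ][1, ]
  }
  list(C = best$C, gamma = best$gamma, rmsecv = best$rmsecv, surface = surface)
}

svr_cv_rmse <- function(X, y, C, gamma, epsilon, pca_variance, scale_range, fold_id) {
  sse <- 0
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    m <- fit_svr(X[tr, , drop = FALSE], y[tr], C = C, gamma = gamma,
                 epsilon = epsilon, pca_variance = pca_variance,
                 scale_range = scale_range)
    pred <- predict(m, X[!tr, , drop = FALSE])
    sse <- sse + sum((y[!tr] - pred)^2)
  }
  sqrt(sse / length(y))
}
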