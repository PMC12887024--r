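#' Asymmetric least squares baseline correction
#'
#' Estimates a smooth baseline by penalized least squares with asymmetric
#' weights (Eilers--Boelens AsLS): points above the current baseline get
#' weight `p`, points below get `1 - p`, so the fit hugs the lower envelope
#' of the spectrum -- appropriate for fluorescence-dominated Raman
#' backgrounds.  The corrected spectrum is `x - baseline`.
#'
#' @param x Numeric intensity vector (finite).
#' @param lambda Smoothness penalty (> 0); larger = stiffer baseline.
#' @param p Asymmetry in (0, 1); small values track the lower envelope.
#' @param maxit Reweighting iterations.
#' @return Corrected intensity vector with the estimated baseline in
#'   attribute `baseline`.
#' @export
baseline_correct <- function(x, lambda = 1e5, p = 0.01, maxit = 10) {
  if (any(!is.finite(x))) stop_invalid("spectrum contains non-finite values")
  if (lambda <= 0) stop_invalid("lambda must be > 0")
  if (p <= 0 || p >= 1) stop_invalid("p must lie in (0, 1)")
  n <- length(x)
  D <- Matrix::bandSparse(n - 2, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2), rep(1, n - 2)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- x
  for (it in seq_len(maxit)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * x))
    w_new <- ifelse(x > z, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  out <- x - z
  attr(out, "baseline") <- z
  out
}

#' Normalize a spectrum
#'
#' @param x Intensity vector.
#' @param mode `"vector"` (unit Euclidean norm), `"area"` (unit trapezoid
#'   integral over `wavenumbers`), or `"minmax"` (range scaled to `[0, 1]`).
#' @param wavenumbers Grid, required for `"area"`.
#' @return Normalized intensity vector.
#' @export
normalize_spectrum <- function(x, mode = c("vector", "area", "minmax"),
                               wavenumbers = NULL) {
  mode <- match.arg(mode)
  if (all(x == 0)) stop_invalid("cannot normalize an all-zero spectrum")
  switch(mode,
    vector = x / sqrt(sum(x^2)),
    area = {
      if (is.null(wavenumbers)) stop_invalid("area normalization needs wavenumbers")
      a <- sum(diff(wavenumbers) * (utils::head(x, -1) + utils::tail(x, -1)) / 2)
      if (a == 0) stop_invalid("zero integral; cannot area-normalize")
      x / a
    },
    minmax = {
      r <- range(x)
      if (r[1] == r[2]) stop_invalid("constant spectrum; cannot minmax-normalize")
      (x - r[1]) / (r[2] - r[1])
    }
  )
}

#' Savitzky--Golay smoothing and derivatives
#'
#' Local polynomial filtering via [signal::sgolayfilt()].  Derivatives are
#' scaled by the grid spacing, so a first derivative is in intensity units
#' per cm\eqn{^{-1}} and a second derivative per cm\eqn{^{-2}}.  Edge
#' channels are handled by polynomial fits on the first/last window, so the
#' channel count is preserved.
#'
#' @param x Intensity vector.
#' @param window Odd window length in channels (> `polyorder`).
#' @param polyorder Polynomial order (>= `deriv`).
#' @param deriv Derivative order: 0 (smoothing), 1 or 2.
#' @param spacing Grid spacing in cm\eqn{^{-1}} (see [grid_spacing()]).
#' @return Filtered vector, same length as `x`.
#' @export
savgol <- function(x, window = 15, polyorder = 3, deriv = 0, spacing = 1) {
  if (window %% 2 != 1) stop_invalid("window must be odd (got %d)", window)
  if (polyorder >= window) stop_invalid("polyorder must be < window")
  if (!deriv %in% 0:2) stop_invalid("deriv must be 0, 1 or 2")
  if (deriv > polyorder) stop_invalid("deriv must be <= polyorder")
  if (window >= length(x)) stop_invalid("window (%d) must be < spectrum length (%d)",
                                        window, length(x))
  as.numeric(signal::sgolayfilt(x, p = polyorder, n = window, m = deriv, ts = spacing))
}

#' Apply a preprocessing method to every spectrum of a dataset
#'
#' Methods mirror the preprocessing comparison of the workflow: raw spectra
#' as control, Savitzky--Golay smoothing (`sg_smooth`), first and second SG
#' derivatives, wavelet denoising (`wavelet_denoise`), and combined
#' AsLS baseline correction + normalization (`baseline_norm`).
#'
#' @param ds A `spectral_dataset`.
#' @param method One of `"raw"`, `"baseline_norm"`, `"sg_smooth"`,
#'   `"first_derivative"`, `"second_derivative"`, `"wavelet_denoise"`.
#' @param window,polyorder SG parameters (see [savgol()]).
#' @param wavelet,level,rule Wavelet parameters (see [wavelet_denoise()]).
#' @param baseline_lambda,baseline_p AsLS parameters (see [baseline_correct()]).
#' @param normalization Normalization mode for `baseline_norm`.
#' @param derivative_input Whether derivatives are taken on `"raw"` spectra
#'   (the derivative itself removes smooth baselines) or on
#'   `"baseline_corrected"` spectra.
#' @return A new `spectral_dataset`; `$preprocessing` records the applied
#'   configuration.
#' @export
apply_preprocessing <- function(ds,
                                method = c("raw", "baseline_norm", "sg_smooth",
                                           "first_derivative", "second_derivative",
                                           "wavelet_denoise"),
                                window = 15, polyorder = 3,
                                wavelet = "sym8", level = 4,
                                rule = c("universal_soft", "universal_hard"),
                                baseline_lambda = 1e5, baseline_p = 0.01,
                                normalization = c("vector", "area", "minmax"),
                                derivative_input = c("raw", "baseline_corrected")) {
  stopifnot(inherits(ds, "spectral_dataset"))
  method <- match.arg(method)
  rule <- match.arg(rule)
  normalization <- match.arg(normalization)
  derivative_input <- match.arg(derivative_input)
  cfg <- list(method = method, window = window, polyorder = polyorder,
              wavelet_name = wavelet, decomposition_level = level,
              threshold_rule = rule, baseline_lambda = baseline_lambda,
              baseline_p = baseline_p, normalization = normalization,
              derivative_input = derivative_input)
  out <- ds
  out$preprocessing <- cfg
  if (method == "raw") return(out)

  sp <- grid_spacing(ds$wavenumbers)
  f <- switch(method,
    baseline_norm = function(x) {
      normalize_spectrum(
        as.numeric(baseline_correct(x, baseline_lambda, baseline_p)),
        mode = normalization, wavenumbers = ds$wavenumbers)
    },
    sg_smooth = function(x) savgol(x, window, polyorder, 0, sp),
    first_derivative = function(x) {
      if (derivative_input == "baseline_corrected") {
        x <- as.numeric(baseline_correct(x, baseline_lambda, baseline_p))
      }
      savgol(x, window, polyorder, 1, sp)
    },
    second_derivative = function(x) {
      if (derivative_input == "baseline_corrected") {
        x <- as.numeric(baseline_correct(x, baseline_lambda, baseline_p))
      }
      savgol(x, window, polyorder, 2, sp)
    },
    wavelet_denoise = function(x) wavelet_denoise(x, wavelet, level, rule)
  )
  out$intensities <- t(apply(ds$intensities, 1, f))
  dimnames(out$intensities) <- dimnames(ds$intensities)
  out
}
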