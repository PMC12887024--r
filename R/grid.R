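#' Wavenumber grid for Raman spectra
#'
#' Builds the evenly spaced Raman-shift axis used throughout the package.
#' The default reproduces the acquisition grid of the workflow this package
#' implements: 1024 channels spanning 500--2000 cm\eqn{^{-1}} inclusive.
#'
#' @param n_points Number of channels (>= 2).
#' @param lo,hi Grid endpoints in cm\eqn{^{-1}}; both are included.
#'
#' @return Numeric vector of strictly increasing wavenumbers of length
#'   `n_points`, with attribute `spacing` (cm\eqn{^{-1}} between channels).
#' @examples
#' g <- make_wavenumber_grid()
#' length(g)    # 1024
#' range(g)     # 500 2000
#' @export
make_wavenumber_grid <- function(n_points = 1024, lo = 500, hi = 2000) {
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 2 ||
      n_points != round(n_points)) {
    stop_invalid("n_points must be an integer >= 2 (got %s)", format(n_points))
  }
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi) {
    stop_invalid("require lo < hi (got lo = %s, hi = %s)", format(lo), format(hi))
  }
  g <- seq(lo, hi, length.out = n_points)
  attr(g, "spacing") <- (hi - lo) / (n_points - 1)
  g
}

grid_spacing <- function(wavenumbers) {
  sp <- attr(wavenumbers, "spacing")
  if (!is.null(sp)) return(sp)
  d <- diff(wavenumbers)
  if (any(d <= 0)) stop_invalid("wavenumbers must be strictly increasing")
  mean(d)
}
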