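# Orthogonal discrete wavelet transform with periodic boundary handling,
# written in-package (no wavelet library ships with the R stack used here).
# Filters are the standard published orthonormal coefficients.

wavelet_filters <- function(name) {
  if (name == "haar") {
    rec_lo <- c(1, 1) / sqrt(2)
  } else if (name == "sym8") {
    # Symlet-8 (least-asymmetric Daubechies, 8 vanishing moments),
    # reconstruction low-pass.
    rec_lo <- c(
       0.0018899503327594609, -0.0003029205147213668, -0.0149522583370482300,
       0.0038087520138906151,  0.0491371796736075060, -0.0272190299170560030,
      -0.0519458381077090400,  0.3644418948353314000,  0.7771857517005235000,
       0.4813596512583722000, -0.0612733590676585240, -0.1432942383508097000,
       0.0076074873249176054,  0.0316950878114929800, -0.0005421323317911481,
      -0.0033824159510061256)
  } else {
    stop_invalid("unsupported wavelet '%s' (available: sym8, haar)", name)
  }
  L <- length(rec_lo)
  rec_hi <- rev(rec_lo) * (-1)^(seq_len(L) - 1)
  list(lo = rec_lo, hi = rec_hi, length = L)
}

# One analysis step: correlate x with the 2-shifted filter bank.
# a[k] = sum_m f[m] x[(2(k-1) + m - 1) mod n + 1]
dwt_step <- function(x, filt) {
  n <- length(x)
  n2 <- n %/% 2L
  base <- (seq_len(n2) - 1L) * 2L
  a <- numeric(n2); d <- numeric(n2)
  for (m in seq_len(filt$length)) {
    xi <- x[(base + (m - 1L)) %% n + 1L]
    a <- a + filt$lo[m] * xi
    d <- d + filt$hi[m] * xi
  }
  list(a = a, d = d)
}

# One synthesis step (transpose of the orthonormal analysis operator).
idwt_step <- function(a, d, filt) {
  n <- 2L * length(a)
  x <- numeric(n)
  base <- (seq_along(a) - 1L) * 2L
  for (m in seq_len(filt$length)) {
    idx <- (base + (m - 1L)) %% n + 1L
    contrib <- filt$lo[m] * a + filt$hi[m] * d
    # scatter-add; idx values are unique within one m
    x[idx] <- x[idx] + contrib
  }
  x
}

dwt_periodic <- function(x, name = "sym8", level = 4) {
  filt <- wavelet_filters(name)
  if (level < 1) stop_invalid("level must be >= 1")
  if (length(x) %% 2^level != 0) {
    stop_invalid("level %d infeasible: length %d not divisible by %d",
                 level, length(x), 2^level)
  }
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    st <- dwt_step(a, filt)
    details[[l]] <- st$d
    a <- st$a
  }
  list(approx = a, details = details, wavelet = name, level = level)
}

idwt_periodic <- function(dec) {
  filt <- wavelet_filters(dec$wavelet)
  a <- dec$approx
  for (l in rev(seq_len(dec$level))) {
    a <- idwt_step(a, dec$details[[l]], filt)
  }
  a
}

#' Wavelet denoising with the universal threshold
#'
#' Multilevel orthogonal DWT (periodized), thresholding of all detail
#' coefficients at the universal threshold
#' \eqn{\hat\sigma \sqrt{2 \ln n}} -- with \eqn{\hat\sigma} estimated from
#' the median absolute deviation of the finest-scale details
#' (MAD / 0.6745) -- and reconstruction to the original length.
#'
#' @param x Intensity vector; length must be divisible by `2^level`.
#' @param wavelet `"sym8"` (default) or `"haar"`.
#' @param level Decomposition depth (>= 1).
#' @param rule `"universal_soft"` (shrink) or `"universal_hard"` (keep/kill).
#' @param threshold Optional fixed threshold overriding the universal rule;
#'   `threshold = 0` returns the input up to reconstruction error.
#' @return Denoised intensity vector, same length as `x`.
#' @export
wavelet_denoise <- function(x, wavelet = "sym8", level = 4,
                            rule = c("universal_soft", "universal_hard"),
                            threshold = NULL) {
  rule <- match.arg(rule)
  dec <- dwt_periodic(x, wavelet, level)
  if (is.null(threshold)) {
    sigma <- stats::median(abs(dec$details[[1]])) / 0.6745
    threshold <- sigma * sqrt(2 * log(length(x)))
  }
  for (l in seq_len(dec$level)) {
    d <- dec$details[[l]]
    dec$details[[l]] <- if (rule == "universal_soft") {
      sign(d) * pmax(abs(d) - threshold, 0)
    } else {
      d * (abs(d) > threshold)
    }
  }
  idwt_periodic(dec)
}
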