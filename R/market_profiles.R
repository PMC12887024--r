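#' Market-level reference-value distributions for crude palm oil
#'
#' Descriptive statistics (range, mean, SD) of peroxide value (PV, meq
#' O2/kg) and iodine value (IV, g I2/100 g) for crude palm oil sold in five
#' Ghanaian open markets: Agbogbloshie (AGB), Dome (DOM), Kaneshie (KAN),
#' Madina (MAD) and Makola (MAK).  These profiles parameterize the synthetic
#' dataset generator: per-sample reference values are drawn from a truncated
#' normal with these moments and bounds.
#'
#' @return A data frame with one row per market and columns `market`,
#'   `pv_mean`, `pv_sd`, `pv_min`, `pv_max`, `iv_mean`, `iv_sd`, `iv_min`,
#'   `iv_max`.
#' @seealso [draw_reference_values()], [generator_config()]
#' @export
market_profiles <- function() {
  data.frame(
    market  = c("AGB", "DOM", "KAN", "MAD", "MAK"),
    pv_mean = c(6.79, 7.58, 8.23, 8.10, 7.79),
    pv_sd   = c(2.08, 1.86, 1.65, 1.87, 2.39),
    pv_min  = c(4.66, 4.36, 4.48, 4.29, 4.57),
    pv_max  = c(11.38, 10.77, 10.65, 11.22, 11.45),
    iv_mean = c(45.57, 46.44, 46.51, 45.04, 47.24),
    iv_sd   = c(1.62, 1.37, 1.98, 2.00, 0.91),
    iv_min  = c(42.69, 43.72, 41.78, 40.89, 45.67),
    iv_max  = c(48.31, 48.49, 48.63, 46.19, 48.69),
    stringsAsFactors = FALSE
  )
}

check_profile <- function(profile) {
  need <- c("market", "pv_mean", "pv_sd", "pv_min", "pv_max",
            "iv_mean", "iv_sd", "iv_min", "iv_max")
  if (!all(need %in% names(profile))) {
    stop_invalid("profile must have fields: %s", paste(need, collapse = ", "))
  }
  with(profile, {
    if (any(pv_sd <= 0) || any(iv_sd <= 0)) stop_invalid("profile SDs must be > 0")
    if (any(pv_min >= pv_mean) || any(pv_mean >= pv_max) ||
        any(iv_min >= iv_mean) || any(iv_mean >= iv_max)) {
      stop_invalid("profile bounds must satisfy min < mean < max")
    }
  })
  invisible(profile)
}

# Mean of a normal(mu, sd) truncated to [lo, hi].
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / Z
}

# Latent location whose truncated mean equals `target` (the printed table
# means describe the *observed*, range-limited samples, so truncation must
# not shift them).  The bracket stays within +-6 sd of the bounds -- wider
# brackets underflow the normal tail.  If the target sits too close to a
# bound for the bracket, fall back to plain truncation at the target.
latent_mu <- function(target, sd, lo, hi) {
  tryCatch(
    stats::uniroot(function(m) truncnorm_mean(m, sd, lo, hi) - target,
                   lower = lo - 6 * sd, upper = hi + 6 * sd,
                   tol = 1e-10)$root,
    error = function(e) target
  )
}

# Truncated-(bivariate-)normal draw by rejection.  Rejection rather than
# clipping keeps the within-bounds distribution shape and avoids probability
# atoms at the range endpoints.
#' Draw reference PV/IV values from a market profile
#'
#' Samples `n` (PV, IV) pairs from truncated normal distributions bounded
#' by the profile's observed ranges.  The latent (pre-truncation) location
#' is adjusted so that the *truncated* mean equals the profile mean --
#' asymmetric range limits would otherwise bias the realized mean away from
#' the printed one.  (The realized SD is the largest the bounded
#' distribution attains for the printed scale, slightly below the printed
#' SD when the range is tight.)  With `correlation != 0` the underlying
#' pair is bivariate normal with that correlation; the default 0 draws PV
#' and IV independently.  Uses the current RNG stream; seed externally (for
#' example via [generator_config()]'s seed in [simulate_dataset()]).
#'
#' @param profile A single row of [market_profiles()] (or a list with the
#'   same fields).
#' @param n Number of samples.
#' @param correlation Latent PV--IV correlation in (-1, 1).
#' @return Data frame with columns `pv` and `iv`, all inside the profile's
#'   `[min, max]` ranges.
#' @export
draw_reference_values <- function(profile, n = 1, correlation = 0) {
  check_profile(profile)
  if (abs(correlation) >= 1) stop_invalid("correlation must lie in (-1, 1)")
  pv <- numeric(n); iv <- numeric(n)
  filled <- 0L
  # sd -> 0 degenerate limit: every draw is the mean
  pv_degen <- profile$pv_sd < .Machine$double.eps
  iv_degen <- profile$iv_sd < .Machine$double.eps
  mu_pv <- if (pv_degen) profile$pv_mean else
    latent_mu(profile$pv_mean, profile$pv_sd, profile$pv_min, profile$pv_max)
  mu_iv <- if (iv_degen) profile$iv_mean else
    latent_mu(profile$iv_mean, profile$iv_sd, profile$iv_min, profile$iv_max)
  while (filled < n) {
    m <- max(2L * (n - filled), 16L)
    z1 <- stats::rnorm(m)
    z2 <- correlation * z1 + sqrt(1 - correlation^2) * stats::rnorm(m)
    cand_pv <- mu_pv + profile$pv_sd * z1
    cand_iv <- mu_iv + profile$iv_sd * z2
    if (pv_degen) cand_pv[] <- profile$pv_mean
    if (iv_degen) cand_iv[] <- profile$iv_mean
    ok <- cand_pv >= profile$pv_min & cand_pv <= profile$pv_max &
          cand_iv >= profile$iv_min & cand_iv <= profile$iv_max
    take <- which(ok)[seq_len(min(sum(ok), n - filled))]
    if (length(take)) {
      idx <- filled + seq_along(take)
      pv[idx] <- cand_pv[take]
      iv[idx] <- cand_iv[take]
      filled <- filled + length(take)
    }
  }
  data.frame(pv = pv, iv = iv)
}
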