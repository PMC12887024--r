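# Synthetic crude-palm-oil Raman generator.  Band positions follow the
# assignments used throughout the analysis: C-H bending / C=C stretching
# modes at 1156, 1287, 1442, 1524, 1602, 1657 cm-1 (the 1287/1602/1657
# cis =C-H and C=C bands carry the unsaturation signal that drives iodine
# value), and the carbonyl / oxidation-product region at 1748-1840 cm-1
# coupled to peroxide value.  A broad fluorescence hump emulates the
# beta-carotene background of crude palm oil.

#' Default Raman peak table for crude palm oil
#'
#' One row per band: `center` and `fwhm` in cm\eqn{^{-1}}, `base_amplitude`
#' in arbitrary intensity units, linear couplings of the band amplitude to
#' the sample's reference values (`pv_coupling` per meq O2/kg,
#' `iv_coupling` per g I2/100 g), and `shape_mix` (fraction of Gaussian in
#' the pseudo-Voigt lineshape).
#'
#' @return Data frame of peak specifications.
#' @export
default_peaks <- function() {
  data.frame(
    center         = c(893, 1156, 1287, 1442, 1524, 1602, 1657, 1748, 1800),
    fwhm           = c(30,   25,   25,   30,   20,   20,   28,   25,   35),
    base_amplitude = c(0.20, 0.60, 0.30, 1.00, 0.40, 0.25, 0.50, 0.30, 0.05),
    pv_coupling    = c(0,    0,    0,    0,    0,    0,    0,    0.030, 0.020),
    iv_coupling    = c(0,    0,    0.008, 0,   0,    0.006, 0.012, 0,   0),
    shape_mix      = 0.7
  )
}

#' Generator configuration for synthetic spectral datasets
#'
#' Bundles everything [simulate_dataset()] needs.  Defaults emulate the
#' acquisition conditions of the study design this package mirrors: 40
#' samples from each of 5 markets (200 total), 1024 channels over 500--2000
#' cm\eqn{^{-1}}, three replicate acquisitions averaged per sample, and a
#' strong broad fluorescence background whose amplitude varies from sample
#' to sample.
#'
#' @param n_per_market Samples drawn per market profile (>= 1).
#' @param profiles Market profile table, see [market_profiles()].
#' @param peaks Peak table, see [default_peaks()].
#' @param n_points,lo,hi Wavenumber grid, see [make_wavenumber_grid()].
#' @param baseline_poly_coeffs Polynomial baseline coefficients
#'   `c(a0, a1, ...)` evaluated in `(wavenumber - lo)`.
#' @param fluorescence_amplitude,fluorescence_center,fluorescence_fwhm
#'   Gaussian fluorescence hump (arbitrary units / cm\eqn{^{-1}}).
#' @param fluorescence_sd Per-sample SD of the fluorescence amplitude
#'   (sample-to-sample baseline variability; truncated at 0).
#' @param fluorescence_center_sd,fluorescence_fwhm_sd Per-sample SD of the
#'   hump position and width: the carotenoid background of crude palm oil
#'   varies in shape between samples, not just in intensity.
#' @param baseline_cv Relative per-sample jitter of each polynomial
#'   baseline coefficient.
#' @param noise_sd SD of i.i.d. Gaussian channel noise per replicate.
#' @param n_replicates Replicate spectra averaged per sample (>= 1).
#' @param pv_iv_correlation Latent PV--IV correlation passed to
#'   [draw_reference_values()].
#' @param seed Integer master seed; fixes the dataset exactly.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_per_market = 40,
                             profiles = market_profiles(),
                             peaks = default_peaks(),
                             n_points = 1024, lo = 500, hi = 2000,
                             baseline_poly_coeffs = c(0.2, 1e-4),
                             fluorescence_amplitude = 5,
                             fluorescence_center = 1100,
                             fluorescence_fwhm = 900,
                             fluorescence_sd = 1,
                             fluorescence_center_sd = 20,
                             fluorescence_fwhm_sd = 50,
                             baseline_cv = 0.2,
                             noise_sd = 0.01,
                             n_replicates = 3,
                             pv_iv_correlation = 0,
                             seed = 42) {
  if (n_per_market < 1) stop_invalid("n_per_market must be >= 1")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (n_replicates < 1) stop_invalid("n_replicates must be >= 1")
  if (is.null(nrow(profiles)) || nrow(profiles) == 0) {
    stop_invalid("profiles must be a non-empty profile table")
  }
  check_profile(profiles)
  if (any(peaks$fwhm <= 0) || any(peaks$base_amplitude < 0)) {
    stop_invalid("peak widths must be > 0 and base amplitudes >= 0")
  }
  cfg <- list(
    n_per_market = as.integer(n_per_market), profiles = profiles, peaks = peaks,
    n_points = as.integer(n_points), lo = lo, hi = hi,
    baseline_poly_coeffs = baseline_poly_coeffs,
    fluorescence_amplitude = fluorescence_amplitude,
    fluorescence_center = fluorescence_center,
    fluorescence_fwhm = fluorescence_fwhm,
    fluorescence_sd = fluorescence_sd,
    fluorescence_center_sd = fluorescence_center_sd,
    fluorescence_fwhm_sd = fluorescence_fwhm_sd,
    baseline_cv = baseline_cv,
    noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
    pv_iv_correlation = pv_iv_correlation, seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  cfg
}

# Unit-height pseudo-Voigt lineshape: mix * Gaussian + (1 - mix) * Lorentzian,
# both parameterized by FWHM.
pseudo_voigt <- function(x, center, fwhm, mix) {
  u <- (x - center) / fwhm
  g <- exp(-4 * log(2) * u^2)
  l <- 1 / (1 + 4 * u^2)
  mix * g + (1 - mix) * l
}

# Deterministic (noise-free) part of one sample's spectrum.
spectrum_signal <- function(grid, pv, iv, config,
                            fluorescence_amplitude = config$fluorescence_amplitude,
                            fluorescence_center = config$fluorescence_center,
                            fluorescence_fwhm = config$fluorescence_fwhm,
                            baseline_coeffs = config$baseline_poly_coeffs) {
  pk <- config$peaks
  amp <- pk$base_amplitude + pk$pv_coupling * pv + pk$iv_coupling * iv
  y <- numeric(length(grid))
  for (j in seq_len(nrow(pk))) {
    y <- y + amp[j] * pseudo_voigt(grid, pk$center[j], pk$fwhm[j], pk$shape_mix[j])
  }
  x0 <- grid - config$lo
  for (d in seq_along(baseline_coeffs)) {
    y <- y + baseline_coeffs[d] * x0^(d - 1)
  }
  y + fluorescence_amplitude *
    exp(-4 * log(2) * ((grid - fluorescence_center) / fluorescence_fwhm)^2)
}

#' Render one synthetic Raman spectrum
#'
#' Intensity = sum of pseudo-Voigt bands (amplitude = base +
#' `pv_coupling * PV` + `iv_coupling * IV`) + polynomial baseline + Gaussian
#' fluorescence hump + i.i.d. Gaussian noise, averaged over
#' `config$n_replicates` replicate renderings (replicate averaging divides
#' the noise variance by the replicate count).  Uses the current RNG
#' stream.  Negative resulting intensities are clipped to 0 and counted in
#' the `clipped` attribute.
#'
#' @param grid Wavenumber grid from [make_wavenumber_grid()].
#' @param refs List or data frame with elements `pv` and `iv`.
#' @param config A [generator_config()].
#' @param fluorescence_amplitude,fluorescence_center,fluorescence_fwhm,baseline_coeffs
#'   Per-sample overrides of the baseline/fluorescence shape (used by
#'   [simulate_dataset()] for sample-to-sample baseline variability).
#' @return Numeric intensity vector the length of `grid`.
#' @export
render_spectrum <- function(grid, refs, config,
                            fluorescence_amplitude = config$fluorescence_amplitude,
                            fluorescence_center = config$fluorescence_center,
                            fluorescence_fwhm = config$fluorescence_fwhm,
                            baseline_coeffs = config$baseline_poly_coeffs) {
  sig <- spectrum_signal(grid, refs$pv, refs$iv, config, fluorescence_amplitude,
                         fluorescence_center, fluorescence_fwhm, baseline_coeffs)
  n <- length(grid)
  acc <- numeric(n)
  for (r in seq_len(config$n_replicates)) {
    rep_i <- sig
    if (config$noise_sd > 0) rep_i <- rep_i + stats::rnorm(n, 0, config$noise_sd)
    acc <- acc + rep_i
  }
  out <- acc / config$n_replicates
  n_neg <- sum(out < 0)
  if (n_neg > 0) {
    warning(sprintf("%d negative intensities clipped to 0", n_neg), call. = FALSE)
    out[out < 0] <- 0
  }
  attr(out, "clipped") <- n_neg
  out
}

#' Simulate a full synthetic spectral dataset
#'
#' Draws `n_per_market` reference-value pairs per market profile, renders
#' each sample's replicate-averaged spectrum, and assembles a
#' `spectral_dataset`: wavenumber grid, intensity matrix (samples x
#' channels), and a metadata table (`sample_id`, `market`, `pv`, `iv`).
#' Identical configurations (including the seed) give identical datasets.
#'
#' @param config A [generator_config()].
#' @return Object of class `spectral_dataset` with elements `wavenumbers`,
#'   `intensities`, `meta`, `preprocessing` (`"raw"`), and `config`.
#' @examples
#' ds <- simulate_dataset(generator_config(n_per_market = 2, n_points = 64))
#' dim(ds$intensities)  # 10 x 64
#' @export
simulate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  grid <- make_wavenumber_grid(config$n_points, config$lo, config$hi)
  n_mkt <- nrow(config$profiles)
  n <- config$n_per_market * n_mkt
  with_seed(config$seed, {
    meta <- vector("list", n_mkt)
    for (m in seq_len(n_mkt)) {
      prof <- config$profiles[m, ]
      refs <- draw_reference_values(prof, config$n_per_market,
                                    correlation = config$pv_iv_correlation)
      meta[[m]] <- data.frame(
        sample_id = sprintf("%s_%03d", prof$market, seq_len(config$n_per_market)),
        market = prof$market, pv = refs$pv, iv = refs$iv,
        stringsAsFactors = FALSE
      )
    }
    meta <- do.call(rbind, meta)
    fl_amp <- pmax(0, stats::rnorm(n, config$fluorescence_amplitude,
                                   config$fluorescence_sd))
    fl_ctr <- stats::rnorm(n, config$fluorescence_center,
                           config$fluorescence_center_sd %||% 0)
    fl_wid <- pmax(config$fluorescence_fwhm / 4,
                   stats::rnorm(n, config$fluorescence_fwhm,
                                config$fluorescence_fwhm_sd %||% 0))
    nb <- length(config$baseline_poly_coeffs)
    bl <- matrix(config$baseline_poly_coeffs, n, nb, byrow = TRUE) *
      (1 + (config$baseline_cv %||% 0) * matrix(stats::rnorm(n * nb), n, nb))
    X <- matrix(0, n, length(grid), dimnames = list(meta$sample_id, NULL))
    for (i in seq_len(n)) {
      X[i, ] <- render_spectrum(grid, meta[i, c("pv", "iv")], config,
                                fluorescence_amplitude = fl_amp[i],
                                fluorescence_center = fl_ctr[i],
                                fluorescence_fwhm = fl_wid[i],
                                baseline_coeffs = bl[i, ])
    }
    structure(
      list(wavenumbers = grid, intensities = X, meta = meta,
           preprocessing = "raw", config = config),
      class = "spectral_dataset"
    )
  })
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf(
    "Spectral dataset: %d samples x %d channels (%.0f-%.0f cm-1), preprocessing: %s\n",
    nrow(x$intensities), ncol(x$intensities),
    min(x$wavenumbers), max(x$wavenumbers),
    if (is.character(x$preprocessing)) x$preprocessing else x$preprocessing$method
  ))
  cat(sprintf("  markets: %s\n", paste(unique(x$meta$market), collapse = ", ")))
  cat(sprintf("  PV range %.2f-%.2f meq O2/kg, IV range %.2f-%.2f g I2/100 g\n",
              min(x$meta$pv), max(x$meta$pv), min(x$meta$iv), max(x$meta$iv)))
  invisible(x)
}

#' Write a spectral dataset to delimited files
#'
#' Writes `spectra.csv` (columns `sample_id`, `market`, then one column per
#' wavenumber), `reference.csv` (`sample_id`, `market`, `pv`, `iv`) and a
#' JSON `manifest.json` recording the seed and generator dimensions.
#'
#' @param ds A `spectral_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_spectral_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- data.frame(sample_id = ds$meta$sample_id, market = ds$meta$market,
                     ds$intensities, check.names = FALSE)
  names(spec)[-(1:2)] <- formatC(ds$wavenumbers, format = "f", digits = 4)
  utils::write.csv(spec, file.path(dir, "spectra.csv"), row.names = FALSE)
  utils::write.csv(ds$meta, file.path(dir, "reference.csv"), row.names = FALSE)
  manifest <- list(
    seed = ds$config$seed %||% NA,
    n_samples = nrow(ds$intensities), n_channels = ncol(ds$intensities),
    wavenumber_range = range(ds$wavenumbers),
    preprocessing = ds$preprocessing
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a generator configuration to YAML or JSON
#'
#' The format follows the file extension (`.yaml`/`.yml` needs the
#' \pkg{yaml} package; anything else is written as JSON).
#' @param config A [generator_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  x <- unclass(config)
  x$profiles <- as.list(x$profiles)
  x$peaks <- as.list(x$peaks)
  if (grepl("\\.ya?ml$", path) && requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a generator configuration written by [write_generator_config()]
#' @param path Input file (`.yaml`/`.yml` or JSON).
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path) && requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  x$profiles <- as.data.frame(x$profiles, stringsAsFactors = FALSE)
  x$peaks <- as.data.frame(x$peaks, stringsAsFactors = FALSE)
  do.call(generator_config, x)
}

#' Read a spectral dataset written by [write_spectral_dataset()]
#' @param dir Directory containing `spectra.csv` and `reference.csv`.
#' @return A `spectral_dataset` (with `config = NULL`).
#' @export
read_spectral_dataset <- function(dir) {
  spec <- utils::read.csv(file.path(dir, "spectra.csv"), check.names = FALSE)
  meta <- utils::read.csv(file.path(dir, "reference.csv"), stringsAsFactors = FALSE)
  wn <- as.numeric(names(spec)[-(1:2)])
  X <- as.matrix(spec[, -(1:2)])
  dimnames(X) <- list(spec$sample_id, NULL)
  structure(
    list(wavenumbers = wn, intensities = X, meta = meta,
         preprocessing = "raw", config = NULL),
    class = "spectral_dataset"
  )
}
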