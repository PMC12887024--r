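test_that("wavenumber grid has exact endpoints, length and spacing", {
  g <- make_wavenumber_grid(1024, 500, 2000)
  expect_length(g, 1024)
  expect_equal(g[1], 500)
  expect_equal(g[1024], 2000)
  expect_true(all(diff(g) > 0))

  expect_equal(as.numeric(make_wavenumber_grid(2, 0, 1)), c(0, 1))
  expect_equal(unique(round(diff(make_wavenumber_grid(5, 500, 2000)), 10)), 375)

  expect_error(make_wavenumber_grid(1, 0, 10), "n_points")
  expect_error(make_wavenumber_grid(10, 5, 5), "lo < hi")
})

test_that("reference draws respect market bounds and match the printed means", {
  prof <- market_profiles()
  agb <- prof[prof$market == "AGB", ]
  draws <- withr::with_seed(1, draw_reference_values(agb, 10000))
  expect_true(all(draws$pv >= agb$pv_min & draws$pv <= agb$pv_max))
  se <- sd(draws$pv) / sqrt(nrow(draws))
  expect_lt(abs(mean(draws$pv) - agb$pv_mean), 3 * se)

  mak <- prof[prof$market == "MAK", ]
  draws <- withr::with_seed(2, draw_reference_values(mak, 10000))
  expect_true(all(draws$iv >= mak$iv_min & draws$iv <= mak$iv_max))
  se <- sd(draws$iv) / sqrt(nrow(draws))
  expect_lt(abs(mean(draws$iv) - mak$iv_mean), 3 * se)
})

test_that("degenerate sd collapses draws to the mean", {
  prof <- market_profiles()[1, ]
  prof$pv_sd <- 1e-300
  prof$iv_sd <- 1e-300
  draws <- withr::with_seed(3, draw_reference_values(prof, 50))
  expect_equal(draws$pv, rep(prof$pv_mean, 50))
  expect_equal(draws$iv, rep(prof$iv_mean, 50))
})

test_that("latent correlation induces the requested sign in the draws", {
  prof <- market_profiles()[2, ]
  draws <- withr::with_seed(4, draw_reference_values(prof, 5000, correlation = -0.8))
  expect_lt(cor(draws$pv, draws$iv), -0.5)
})

test_that("peak couplings make intensity affine in the coupled reference value", {
  grid <- make_wavenumber_grid(256, 500, 2000)
  pk <- default_peaks()
  cfg <- generator_config(peaks = pk, noise_sd = 0, n_points = 256,
                          fluorescence_sd = 0, baseline_cv = 0,
                          fluorescence_center_sd = 0, fluorescence_fwhm_sd = 0)
  ch <- which.min(abs(grid - 1748))
  at_pv <- function(pv) render_spectrum(grid, list(pv = pv, iv = 46), cfg)[ch]
  i1 <- at_pv(5); i2 <- at_pv(8); i3 <- at_pv(11)
  expect_gt(i2, i1)
  expect_gt(i3, i2)
  # affine: equal increments in PV give equal increments in intensity
  expect_equal(i3 - i2, i2 - i1, tolerance = 1e-12)
  # slope equals the summed couplings weighted by the lineshape at that channel
  pv_shape <- function(x, c0, w, mix) {
    u <- (x - c0) / w
    mix * exp(-4 * log(2) * u^2) + (1 - mix) / (1 + 4 * u^2)
  }
  slope <- (i2 - i1) / 3
  expected <- sum(pk$pv_coupling *
                    pv_shape(grid[ch], pk$center, pk$fwhm, pk$shape_mix))
  expect_equal(slope, expected, tolerance = 1e-12)
})

test_that("zero couplings decouple the spectrum from the reference values", {
  pk <- default_peaks()
  pk$pv_coupling <- 0
  pk$iv_coupling <- 0
  grid <- make_wavenumber_grid(128, 500, 2000)
  cfg <- generator_config(peaks = pk, noise_sd = 0, n_points = 128)
  s1 <- render_spectrum(grid, list(pv = 5, iv = 42), cfg)
  s2 <- render_spectrum(grid, list(pv = 11, iv = 48), cfg)
  expect_equal(as.numeric(s1), as.numeric(s2))
})

test_that("replicate averaging reduces channel noise variance by the replicate count", {
  grid <- make_wavenumber_grid(8, 500, 2000)
  # large constant offset keeps intensities away from the clip-at-zero floor
  cfg <- generator_config(noise_sd = 0.5, n_replicates = 3, n_points = 8,
                          baseline_poly_coeffs = c(10, 0))
  vals <- withr::with_seed(5, {
    replicate(1500, render_spectrum(grid, list(pv = 7, iv = 46), cfg)[4])
  })
  expect_equal(var(vals), 0.5^2 / 3, tolerance = 0.15)
})

test_that("simulated datasets have exact per-market bookkeeping and are seed-reproducible", {
  ds <- simulate_dataset(generator_config(n_per_market = 40, n_points = 64))
  expect_equal(nrow(ds$intensities), 200)
  expect_equal(as.numeric(table(ds$meta$market)), rep(40, 5))
  prof <- market_profiles()
  for (m in prof$market) {
    rows <- ds$meta[ds$meta$market == m, ]
    pr <- prof[prof$market == m, ]
    expect_true(all(rows$pv >= pr$pv_min & rows$pv <= pr$pv_max))
    expect_true(all(rows$iv >= pr$iv_min & rows$iv <= pr$iv_max))
  }

  ds2 <- simulate_dataset(generator_config(n_per_market = 40, n_points = 64))
  expect_identical(ds$intensities, ds2$intensities)
  expect_identical(ds$meta, ds2$meta)

  ds3 <- simulate_dataset(generator_config(n_per_market = 1, n_points = 32))
  expect_equal(nrow(ds3$intensities), 5)
  expect_setequal(ds3$meta$market, prof$market)
})

test_that("generator configs round-trip through YAML and JSON", {
  cfg <- tiny_config(seed = 15, noise_sd = 0.02)
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_generator_config(cfg, path)
    back <- read_generator_config(path)
    expect_equal(back$noise_sd, 0.02)
    expect_equal(back$profiles, cfg$profiles)
    # same config => same dataset
    expect_identical(simulate_dataset(back)$intensities,
                     simulate_dataset(cfg)$intensities)
  }
})

test_that("dataset round-trips through the CSV writer", {
  ds <- tiny_dataset()
  dir <- withr::local_tempdir()
  write_spectral_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "spectra.csv")))
  expect_true(file.exists(file.path(dir, "reference.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_spectral_dataset(dir)
  expect_equal(back$meta$pv, ds$meta$pv, tolerance = 1e-12)
  expect_equal(unname(back$intensities), unname(ds$intensities), tolerance = 1e-12)
  expect_equal(back$wavenumbers, as.numeric(ds$wavenumbers), tolerance = 1e-4)
})
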