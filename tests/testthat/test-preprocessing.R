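test_that("AsLS baseline correction recovers a ramp-confounded peak", {
  x <- seq(500, 2000, length.out = 512)
  peak <- 2 * exp(-((x - 1200) / 15)^2)
  ramp <- 0.002 * (x - 500) + 0.5
  corrected <- baseline_correct(peak + ramp)
  expect_equal(max(corrected), max(peak), tolerance = 0.05)
  # idempotence: a second pass changes little
  twice <- baseline_correct(as.numeric(corrected))
  rel <- sqrt(mean((as.numeric(twice) - as.numeric(corrected))^2)) /
    max(abs(corrected))
  expect_lt(rel, 0.01)
  # null input stays null
  expect_equal(as.numeric(baseline_correct(rep(0, 100))), rep(0, 100))
  expect_error(baseline_correct(c(1, NA, 2)), "non-finite")
})

test_that("normalization modes satisfy their defining identities", {
  withr::with_seed(21, {
    x <- abs(rnorm(200)) + 0.1
    expect_equal(sum(normalize_spectrum(x, "vector")^2), 1, tolerance = 1e-12)
    # scale invariance
    expect_equal(normalize_spectrum(5.3 * x, "vector"),
                 normalize_spectrum(x, "vector"), tolerance = 1e-12)
    # idempotence
    expect_equal(normalize_spectrum(normalize_spectrum(x, "vector"), "vector"),
                 normalize_spectrum(x, "vector"), tolerance = 1e-12)
  })
  # unit rectangle over a 10 cm-1 span integrates to 10 -> values 0.1
  wn <- seq(0, 10, length.out = 101)
  rect <- rep(1, 101)
  expect_equal(normalize_spectrum(rect, "area", wn), rep(0.1, 101),
               tolerance = 1e-12)
  mm <- normalize_spectrum(sin(seq_len(50)), "minmax")
  expect_equal(range(mm), c(0, 1))
  expect_error(normalize_spectrum(rep(0, 10), "vector"), "all-zero")
})

test_that("Savitzky-Golay filtering reproduces polynomial derivatives exactly", {
  g <- make_wavenumber_grid(300, 500, 2000)
  sp <- diff(g)[1]
  a <- 3e-6
  quad <- a * g^2
  d2 <- savgol(quad, 15, 3, 2, spacing = sp)
  interior <- 20:280
  expect_equal(d2[interior], rep(2 * a, length(interior)), tolerance = 1e-8)
  # first derivative of a constant is zero
  expect_equal(savgol(rep(4, 100), 15, 3, 1), rep(0, 100), tolerance = 1e-10)
  # second derivative removes a linear baseline entirely
  line <- 0.01 * g + 3
  expect_equal(savgol(line, 15, 3, 2, spacing = sp)[interior],
               rep(0, length(interior)), tolerance = 1e-10)
  expect_error(savgol(quad, 14, 3, 1), "odd")
  expect_error(savgol(quad, 15, 3, 3), "deriv")
  expect_error(savgol(rep(1, 10), 15, 3, 0), "length")
})

test_that("wavelet denoising is a perfect-reconstruction transform at zero threshold", {
  x <- sin(seq(0, 20, length.out = 512)) + seq(0, 2, length.out = 512)
  for (w in c("sym8", "haar")) {
    rec <- wavelet_denoise(x, w, 4, threshold = 0)
    expect_lt(sqrt(mean((rec - x)^2)), 1e-8)
  }
  expect_error(wavelet_denoise(rnorm(100), "sym8", 3), "infeasible")
})

test_that("universal-threshold denoising shrinks noise but preserves smooth peaks", {
  # variance reduction on pure noise, Monte Carlo
  ratios <- withr::with_seed(22, {
    replicate(500, {
      x <- rnorm(256)
      var(wavelet_denoise(x, "sym8", 4)) / var(x)
    })
  })
  expect_lt(mean(ratios), 1)
  expect_lt(quantile(ratios, 0.95), 1)

  # noiseless smooth peak passes through nearly unchanged
  g <- seq(500, 2000, length.out = 512)
  peak <- 3 * exp(-((g - 1200) / 60)^2)
  den <- wavelet_denoise(peak, "sym8", 4)
  expect_lt(sqrt(mean((den - peak)^2)), 0.02 * max(peak))
})

test_that("dataset-level preprocessing preserves shape and records its config", {
  ds <- tiny_dataset()
  raw <- apply_preprocessing(ds, "raw")
  expect_identical(raw$intensities, ds$intensities)
  expect_equal(raw$preprocessing$method, "raw")

  d2 <- apply_preprocessing(ds, "second_derivative", window = 11, polyorder = 3)
  expect_equal(dim(d2$intensities), dim(ds$intensities))
  expect_equal(d2$preprocessing$method, "second_derivative")
  expect_equal(d2$preprocessing$window, 11)

  # per-sample additive offsets on a shared linear baseline vanish under the
  # second derivative: between-sample variance of channel means goes to ~0
  offs <- seq(-1, 1, length.out = nrow(ds$intensities))
  shifted <- ds
  shifted$intensities <- ds$intensities + outer(offs, rep(1, ncol(ds$intensities)))
  d2s <- apply_preprocessing(shifted, "second_derivative")
  expect_lt(var(rowMeans(d2s$intensities) - rowMeans(d2$intensities)), 1e-10)
})
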