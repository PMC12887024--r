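# Reduced-size experiment runs: 40 samples x 256 channels with a small GA
# and a coarse SVR grid keep the full grid fast while exercising every
# stage end to end.

small_experiment_config <- function(seed = 17, ...) {
  experiment_config(
    master_seed = seed,
    cars = list(n_iterations = 20),
    ga = list(population_size = 16, n_generations = 15, n_runs = 3,
              init_prob = 0.2),
    svm = list(C_grid = 2^seq(-2, 8, 2), gamma_grid = 2^seq(-8, 2, 2),
               refine = FALSE),
    rf = list(n_trees = 100),
    ...
  )
}

test_that("a preprocessing comparison row set is complete and its winner is the RPD argmax", {
  ds <- tiny_dataset(seed = 81)
  single <- compare_preprocessing(ds, methods = "raw")
  expect_equal(nrow(single), 1)
  expect_equal(attr(single, "winner"), "raw")

  tab <- compare_preprocessing(ds, methods = c("raw", "second_derivative",
                                               "sg_smooth"))
  expect_equal(nrow(tab), 3)
  expect_equal(attr(tab, "winner"), tab$model[which.max(tab$RPD)])
})

test_that("a strong sample-to-sample baseline confound favors derivative preprocessing", {
  # constructed confound: per-sample random smooth baseline curves spanning
  # more directions (15 broad Gaussians) than the PLS component budget, so
  # a linear model on raw spectra cannot project them all out -- while the
  # second derivative removes them because they are smooth
  ds <- simulate_dataset(generator_config(seed = 99))
  withr::with_seed(1234, {
    K <- 15
    centers <- seq(500, 2000, length.out = K)
    Phi <- sapply(centers, function(c0) exp(-((ds$wavenumbers - c0) / 150)^2))
    A <- matrix(rnorm(nrow(ds$intensities) * K, sd = 0.4), ncol = K)
    ds$intensities <- ds$intensities + A %*% t(Phi)
  })
  tab <- compare_preprocessing(ds, methods = c("raw", "second_derivative"))
  r <- function(m) tab$RPD[tab$model == m]
  expect_gt(r("second_derivative"), r("raw"))
})

test_that("the reduced experiment grid yields 12 paired, reproducible model rows", {
  ds <- simulate_dataset(generator_config(n_per_market = 8, n_points = 256,
                                          seed = 82))
  cfg <- small_experiment_config(parameters = "pv")
  res <- run_experiment(ds, cfg)
  expect_equal(length(res$errors), 0)
  expect_equal(nrow(res$table), 12)
  expect_setequal(
    res$table$model,
    c("PLS", "SVM", "RF",
      "CARS-PLS", "CARS-SVM", "CARS-RF",
      "UVE-PLS", "UVE-SVM", "UVE-RF",
      "GA-PLS", "GA-SVM", "GA-RF"))
  # paired design: every row shares the single partition
  expect_true(all(res$table$n_variables[res$table$model %in%
                                          c("PLS", "SVM", "RF")] == 256))
  sel_counts <- vapply(res$selections, function(s) length(s$selected), integer(1))
  for (sel in c("CARS", "UVE", "GA")) {
    rows <- grep(paste0("^", sel, "-"), res$table$model)
    expect_true(all(res$table$n_variables[rows] == sel_counts[[paste0("pv.", sel)]]))
  }

  # every table cell is recomputable from the emitted per-sample predictions
  for (key in c("pv.PLS", "pv.GA-RF")) {
    rep <- res$reports[[key]]
    pr <- rep$predictions
    prd <- pr[pr$set == "prediction", ]
    row <- res$table[res$table$model == sub("^pv\\.", "", key), ]
    expect_equal(row$Rp, cor(prd$reference, prd$predicted), tolerance = 1e-12)
    expect_equal(row$RMSEP, sqrt(mean((prd$reference - prd$predicted)^2)),
                 tolerance = 1e-12)
    expect_equal(row$RPD, sd(prd$reference) / row$RMSEP, tolerance = 1e-12)
  }

  res2 <- run_experiment(ds, cfg)
  expect_identical(res$table, res2$table)
})

test_that("experiment artifacts are written and re-readable", {
  ds <- simulate_dataset(generator_config(n_per_market = 4, n_points = 128,
                                          seed = 83))
  dir <- withr::local_tempdir()
  cfg <- small_experiment_config(parameters = "pv",
                                 selectors = "UVE", algorithms = c("PLS", "RF"),
                                 output_dir = dir)
  res <- run_experiment(ds, cfg)
  expect_true(file.exists(file.path(dir, "experiment_table.csv")))
  expect_true(file.exists(file.path(dir, "predictions.csv")))
  expect_true(file.exists(file.path(dir, "experiment_manifest.json")))
  expect_true(file.exists(file.path(dir, "selection_pv.UVE.json")))
  tab <- read.csv(file.path(dir, "experiment_table.csv"))
  expect_equal(nrow(tab), 4)
  sel <- jsonlite::read_json(file.path(dir, "selection_pv.UVE.json"),
                             simplifyVector = TRUE)
  expect_equal(sort(sel$selected), res$selections[["pv.UVE"]]$selected)
})
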