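test_that("partition sizes follow the floor(2n/3) rule", {
  p200 <- partition_samples(200, method = "random")
  expect_equal(length(p200$calibration), 133)
  expect_equal(length(p200$prediction), 67)
  p3 <- partition_samples(3, method = "random")
  expect_equal(c(length(p3$calibration), length(p3$prediction)), c(2, 1))
  p10 <- partition_samples(10, method = "random")
  expect_equal(length(p10$calibration), 6)
  expect_error(partition_samples(2, method = "random"), "3")

  ds <- tiny_dataset()
  ks <- partition_samples(ds)
  n <- nrow(ds$intensities)
  expect_equal(length(ks$calibration), floor(2 * n / 3))
  expect_setequal(c(ks$calibration, ks$prediction), seq_len(n))
})

test_that("Kennard-Stone is deterministic and row-order invariant", {
  ds <- tiny_dataset()
  p1 <- partition_samples(ds)
  p2 <- partition_samples(ds)
  expect_identical(p1$calibration, p2$calibration)

  # permute the rows; the selected *samples* must be identical
  perm <- withr::with_seed(71, sample(nrow(ds$intensities)))
  shuffled <- ds
  shuffled$intensities <- ds$intensities[perm, ]
  shuffled$meta <- ds$meta[perm, ]
  p3 <- partition_samples(shuffled)
  expect_setequal(shuffled$meta$sample_id[p3$calibration],
                  ds$meta$sample_id[p1$calibration])

  # maximin property: the first two selected points realize the max distance
  X <- ds$intensities
  sel <- kennard_stone(X, 5)
  D <- as.matrix(dist(X))
  expect_equal(D[sel[1], sel[2]], max(D))
})

test_that("the metric suite matches hand-computed values", {
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1.0)
  y <- c(1, 2, 3, 4)
  expect_equal(pearson_r(y, -(y - mean(y))), -1.0)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8)),
               0.99085, tolerance = 1e-4)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")

  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0, 0), c(2, 2, 2)), 2)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_error(rmse(1:3, 1:4), "mismatch")

  expect_equal(rpd(c(1, 2, 3), sd(c(1, 2, 3))), 1.0)
  expect_equal(rpd(c(0, 4), 0.5), sd(c(0, 4)) / 0.5)  # sd 2, rmsep 0.5 -> 4.0 scaled
  expect_error(rpd(c(1, 2), 0), "infinite")
  expect_error(rpd(c(2, 2), 1), "constant")

  expect_equal(classify_rpd(3.0), "excellent")
  expect_equal(classify_rpd(2.5), "acceptable")
  expect_equal(classify_rpd(1.99), "limited")
  expect_equal(classify_rpd(2.0), "acceptable")
  expect_error(classify_rpd(0), "RPD")
})

test_that("evaluation reports are self-consistent with their stored predictions", {
  ds <- tiny_dataset()
  pp <- apply_preprocessing(ds, "second_derivative")
  part <- partition_samples(ds)
  Xc <- pp$intensities[part$calibration, ]
  yc <- pp$meta$pv[part$calibration]
  m <- fit_pls(Xc, yc, 3)
  rep <- evaluate_model(m, part, pp, "pv")

  pr <- rep$predictions
  cal <- pr[pr$set == "calibration", ]
  prd <- pr[pr$set == "prediction", ]
  expect_equal(rep$Rc, cor(cal$reference, cal$predicted), tolerance = 1e-12)
  expect_equal(rep$RMSEC, sqrt(mean((cal$reference - cal$predicted)^2)),
               tolerance = 1e-12)
  expect_equal(rep$Rp, cor(prd$reference, prd$predicted), tolerance = 1e-12)
  expect_equal(rep$RMSEP, sqrt(mean((prd$reference - prd$predicted)^2)),
               tolerance = 1e-12)
  expect_equal(rep$RPD, sd(prd$reference) / rep$RMSEP, tolerance = 1e-12)
  expect_equal(rep$n_cal, length(part$calibration))
  expect_equal(rep$n_pred, length(part$prediction))

  # a model that memorizes the calibration responses scores a perfect
  # calibration row (prediction rows stay imperfect so RPD is defined)
  oracle <- structure(list(n_variables = ncol(pp$intensities)),
                      class = c("memorizer", "palm_model"))
  registerS3method("predict", "memorizer",
                   function(object, newdata, ...) {
                     idx <- match(apply(round(newdata, 6), 1, paste, collapse = ","),
                                  apply(round(pp$intensities, 6), 1, paste, collapse = ","))
                     out <- pp$meta$pv[idx]
                     out[idx %in% part$prediction] <-
                       out[idx %in% part$prediction] + 0.3
                     out
                   })
  rep2 <- evaluate_model(oracle, part, pp, "pv")
  expect_equal(rep2$Rc, 1.0)
  expect_equal(rep2$RMSEC, 0)

  # a constant mean-predictor makes the prediction correlation undefined,
  # which surfaces as an error rather than NA
  registerS3method("predict", "meanpred",
                   function(object, newdata, ...) rep(3, nrow(newdata)))
  flat <- structure(list(n_variables = ncol(pp$intensities)),
                    class = c("meanpred", "palm_model"))
  expect_error(evaluate_model(flat, part, pp, "pv"), "constant")
})

test_that("dimensionality reporting uses half-up rounding to one decimal", {
  expect_equal(dimensionality_report(66, 1024),
               list(retained_pct = 6.4, reduction_pct = 93.6))
  expect_equal(dimensionality_report(45, 1024)$retained_pct, 4.4)
  expect_equal(dimensionality_report(148, 1024)$retained_pct, 14.5)
  expect_equal(dimensionality_report(140, 1024)$retained_pct, 13.7)
  expect_equal(dimensionality_report(1024, 1024),
               list(retained_pct = 100.0, reduction_pct = 0.0))
  expect_error(dimensionality_report(0, 1024), "n_selected")
})
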