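# Orchestration of the full 12-model study: {PLS, SVM, RF} x {full
# spectrum, CARS, UVE, GA} per quality parameter, on one shared partition.

#' Dimensionality-reduction report
#'
#' Percentage of variables retained and eliminated by a selection, rounded
#' half-up to one decimal (e.g. 66 of 1024 variables: 6.4% retained, 93.6%
#' reduction).
#'
#' @param n_selected Selected variable count, `1 <= n_selected <= p`.
#' @param p Total variable count.
#' @return List with `retained_pct` and `reduction_pct`.
#' @export
dimensionality_report <- function(n_selected, p) {
  if (any(n_selected < 1) || any(n_selected > p)) {
    stop_invalid("n_selected must lie in [1, p]")
  }
  list(retained_pct = round_half_up(100 * n_selected / p, 1),
       reduction_pct = round_half_up(100 * (p - n_selected) / p, 1))
}

#' Experiment configuration
#'
#' Controls for [run_experiment()].  The default grid enumerates exactly 12
#' models per parameter: 3 regression algorithms times full-spectrum + 3
#' selectors.  `master_seed` derives every stage's sub-seed by fixed
#' offsets (selection: +101/+202/+303, SVR folds: +404, RF: +505, each
#' shifted by +1000 for the second parameter), so a rerun is byte-identical.
#'
#' @param parameters Which reference values to model.
#' @param preprocessing Method name passed to [apply_preprocessing()], or
#'   `"auto"` to pick the [compare_preprocessing()] winner on the first
#'   parameter.
#' @param selectors Subset of `c("CARS", "UVE", "GA")`.
#' @param algorithms Subset of `c("PLS", "SVM", "RF")`.
#' @param partition_method,master_seed Partitioning and seeding.
#' @param max_pls_components Bound for all component choices.
#' @param cars,uve,ga Named lists overriding selector defaults.
#' @param svm,rf Named lists overriding model defaults (e.g. `svm$C_grid`).
#' @param output_dir If non-NULL, artifacts (tables, selections,
#'   hyperparameter surfaces, per-sample predictions) are written there.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(parameters = c("pv", "iv"),
                              preprocessing = "second_derivative",
                              selectors = c("CARS", "UVE", "GA"),
                              algorithms = c("PLS", "SVM", "RF"),
                              partition_method = "kennard_stone",
                              master_seed = 17,
                              max_pls_components = 10,
                              cars = list(), uve = list(), ga = list(),
                              svm = list(), rf = list(),
                              output_dir = NULL) {
  structure(list(parameters = parameters, preprocessing = preprocessing,
                 selectors = selectors, algorithms = algorithms,
                 partition_method = partition_method,
                 master_seed = as.integer(master_seed),
                 max_pls_components = max_pls_components,
                 cars = cars, uve = uve, ga = ga, svm = svm, rf = rf,
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Compare preprocessing methods with a PLS model
#'
#' Fits one cross-validation-tuned PLS model per preprocessing method on an
#' identical partition and reports the standard metric row for each; the
#' winner (highest prediction-set RPD) is recorded in the `winner`
#' attribute.
#'
#' @param dataset A raw `spectral_dataset`.
#' @param methods Preprocessing method names (see [apply_preprocessing()]).
#' @param parameter `"pv"` or `"iv"`.
#' @param partition Optional precomputed [partition_samples()] result
#'   (default: Kennard--Stone on the raw spectra).
#' @param max_pls_components CV bound for the component count.
#' @return Data frame of class `experiment_table`, one row per method.
#' @export
compare_preprocessing <- function(dataset,
                                  methods = c("raw", "first_derivative",
                                              "second_derivative",
                                              "wavelet_denoise", "sg_smooth"),
                                  parameter = c("pv", "iv"),
                                  partition = NULL,
                                  max_pls_components = 10) {
  parameter <- match.arg(parameter)
  if (!length(methods)) stop_invalid("need at least one method")
  if (is.null(partition)) partition <- partition_samples(dataset)
  rows <- lapply(methods, function(m) {
    pp <- apply_preprocessing(dataset, method = m)
    Xc <- pp$intensities[partition$calibration, , drop = FALSE]
    yc <- pp$meta[[parameter]][partition$calibration]
    k <- choose_pls_components(Xc, yc, max_pls_components)
    fit <- fit_pls(Xc, yc, k)
    rep <- evaluate_model(fit, partition, pp, parameter, model_name = m)
    as.data.frame(rep)
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("experiment_table", class(tab))
  attr(tab, "winner") <- tab$model[which.max(tab$RPD)]
  tab
}

#' Run the full multi-model calibration experiment
#'
#' For each parameter: applies the configured preprocessing, partitions the
#' samples (Kennard--Stone on the raw spectra by default), runs each
#' enabled selector on the calibration samples only, then fits and
#' evaluates every algorithm on the full spectrum and on each selected
#' subset -- the default configuration is the 12-model grid.  The same
#' partition and the same selected variables feed all regressors, so rows
#' are paired comparisons.  PLS component counts are cross-validated, SVR
#' hyperparameters grid-searched per subset, RF uses its configured
#' defaults.  A failed stage yields an `error` entry for its row; the
#' remaining rows are still produced.
#'
#' @param dataset A raw `spectral_dataset`.
#' @param config An [experiment_config()].
#' @return List of class `experiment_result` with elements `table` (the
#'   combined `experiment_table`), `selections`, `svr_surfaces`, `reports`,
#'   `partition`, `preprocessing`, `errors`.
#' @export
run_experiment <- function(dataset, config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  seed0 <- config$master_seed

  prep_method <- config$preprocessing
  prep_table <- NULL
  if (identical(prep_method, "auto")) {
    prep_table <- compare_preprocessing(dataset, parameter = config$parameters[1],
                                        max_pls_components = config$max_pls_components)
    prep_method <- attr(prep_table, "winner")
  }
  pp <- apply_preprocessing(dataset, method = prep_method)
  part <- partition_samples(dataset, method = config$partition_method,
                            seed = seed0)
  cal <- part$calibration

  selections <- list(); surfaces <- list(); reports <- list(); errors <- list()
  rows <- list()
  p <- ncol(pp$intensities)

  for (pi in seq_along(config$parameters)) {
    param <- config$parameters[pi]
    poff <- 1000L * (pi - 1L)
    y <- pp$meta[[param]]
    Xc <- pp$intensities[cal, , drop = FALSE]
    yc <- y[cal]

    subsets <- list(full = seq_len(p))
    for (sel in config$selectors) {
      key <- paste0(param, ".", sel)
      res <- tryCatch(switch(sel,
        CARS = do.call(cars_select, c(list(X = Xc, y = yc,
                 max_pls_components = config$max_pls_components,
                 seed = seed0 + 101L + poff), config$cars)),
        UVE = do.call(uve_select, c(list(X = Xc, y = yc,
                 max_pls_components = config$max_pls_components,
                 seed = seed0 + 202L + poff), config$uve)),
        GA = do.call(ga_select, c(list(X = Xc, y = yc,
                 max_pls_components = config$max_pls_components,
                 seed = seed0 + 303L + poff), config$ga))),
        error = function(e) e)
      if (inherits(res, "error")) {
        errors[[key]] <- conditionMessage(res)
      } else {
        selections[[key]] <- res
        subsets[[sel]] <- res$selected
      }
    }

    for (sub_name in names(subsets)) {
      sub <- subsets[[sub_name]]
      Xsub <- Xc[, sub, drop = FALSE]
      for (alg in config$algorithms) {
        model_name <- if (sub_name == "full") alg else paste0(sub_name, "-", alg)
        key <- paste0(param, ".", model_name)
        row <- tryCatch({
          model <- switch(alg,
            PLS = {
              k <- choose_pls_components(Xsub, yc, config$max_pls_components)
              fit_pls(Xsub, yc, k)
            },
            SVM = {
              gs_args <- c(list(X = Xsub, y = yc,
                                fold_id = make_folds(length(yc), 5,
                                                     seed = seed0 + 404L + poff)),
                           config$svm)
              gs <- do.call(grid_search_svr, gs_args)
              surfaces[[key]] <- gs$surface
              fit_svr(Xsub, yc, C = gs$C, gamma = gs$gamma,
                      epsilon = config$svm$epsilon %||% 0.1,
                      pca_variance = config$svm$pca_variance %||% 0.95)
            },
            RF = do.call(fit_rf, c(list(X = Xsub, y = yc,
                                        seed = seed0 + 505L + poff),
                                   config$rf)))
          rep <- evaluate_model(model, part, pp, param, selected = sub,
                                model_name = model_name)
          reports[[key]] <- rep
          as.data.frame(rep)
        }, error = function(e) e)
        if (inherits(row, "error")) {
          errors[[key]] <- conditionMessage(row)
        } else {
          rows[[key]] <- row
        }
      }
    }
  }

  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  class(tab) <- c("experiment_table", class(tab))
  out <- structure(
    list(table = tab, selections = selections, svr_surfaces = surfaces,
         reports = reports, partition = part,
         preprocessing = prep_method, preprocessing_table = prep_table,
         errors = errors, config = config),
    class = "experiment_result"
  )
  if (!is.null(config$output_dir)) write_experiment(out, config$output_dir)
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment: %d model rows, preprocessing = %s, %d/%d split\n",
              nrow(x$table), x$preprocessing,
              length(x$partition$calibration), length(x$partition$prediction)))
  print(format_experiment_table(x$table))
  if (length(x$errors)) {
    cat("Failed rows:\n")
    for (k in names(x$errors)) cat(sprintf("  %s: %s\n", k, x$errors[[k]]))
  }
  invisible(x)
}

#' Format an experiment table for display
#'
#' Rounds metrics to the 4 decimals conventional for calibration tables.
#' @param tab An `experiment_table`.
#' @return Data frame with formatted numeric columns.
#' @export
format_experiment_table <- function(tab) {
  out <- as.data.frame(tab)
  for (cn in c("Rc", "RMSEC", "Rp", "RMSEP", "RPD")) {
    out[[cn]] <- round(out[[cn]], 4)
  }
  out$predictions <- NULL
  out
}

write_experiment <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(format_experiment_table(result$table),
                   file.path(dir, "experiment_table.csv"), row.names = FALSE)
  for (k in names(result$selections)) {
    write_selection_json(result$selections[[k]],
                         file.path(dir, paste0("selection_", k, ".json")))
  }
  for (k in names(result$svr_surfaces)) {
    utils::write.csv(result$svr_surfaces[[k]],
                     file.path(dir, paste0("svr_surface_", k, ".csv")),
                     row.names = FALSE)
  }
  preds <- do.call(rbind, lapply(names(result$reports), function(k) {
    cbind(model = k, result$reports[[k]]$predictions)
  }))
  utils::write.csv(preds, file.path(dir, "predictions.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(master_seed = result$config$master_seed,
         preprocessing = result$preprocessing,
         calibration = result$partition$calibration,
         prediction = result$partition$prediction,
         errors = result$errors),
    file.path(dir, "experiment_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
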