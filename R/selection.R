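# Wavelength selection over the cross-validated SIMPLS engine.

new_selection_result <- function(method, selected, seed, ...) {
  if (!length(selected)) stop_invalid("%s selection is empty", method)
  structure(
    c(list(method = method, selected = sort(unique(as.integer(selected))),
           seed = seed), list(...)),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("%s selection: %d variables (seed %d)\n",
              x$method, length(x$selected), x$seed))
  invisible(x)
}

#' Serialize a selection result to JSON
#' @param result A `selection_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

validate_selection_input <- function(X, y, cv_folds) {
  X <- as_matrix_x(X)
  if (nrow(X) != length(y)) stop_invalid("nrow(X) != length(y)")
  if (nrow(X) < cv_folds) stop_invalid("need at least cv_folds = %d samples", cv_folds)
  if (stats::sd(y) == 0) stop_invalid("constant response; nothing to select for")
  if (all(apply(X, 2, stats::sd) == 0)) stop_invalid("X has no variance")
  X
}

#' CARS exponential-decay retention ratio
#'
#' Fraction of variables force-retained at iteration `i` of an `N`-iteration
#' CARS run on `p` variables: \eqn{r_i = a e^{-k i}} with
#' \eqn{k = \ln(p/2)/(N-1)} and \eqn{a = e^{k}}, so that \eqn{r_1 = 1} (all
#' variables survive the first iteration) and \eqn{r_N = 2/p} (two variables
#' survive the last).
#'
#' @param i Iteration, `1 <= i <= N`.
#' @param N Total iterations (>= 2).
#' @param p Number of variables (> 2).
#' @return Retention fraction in (0, 1].
#' @export
edf_retention_ratio <- function(i, N, p) {
  if (p <= 2) stop_invalid("p must be > 2")
  if (any(i < 1) || any(i > N)) stop_invalid("i must lie in [1, N]")
  k <- log(p / 2) / (N - 1)
  exp(k) * exp(-k * i)
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Each iteration fits a Monte-Carlo PLS model on a random subset of the
#' calibration samples, force-retains the top \eqn{\lceil r_i p \rceil}
#' variables by absolute regression coefficient (exponentially decaying
#' [edf_retention_ratio()]), then applies adaptive reweighted sampling --
#' a weighted draw with replacement, probability proportional to the
#' coefficient magnitude -- among the survivors.  The surviving set's
#' cross-validated RMSE is recorded, and the set from the iteration with
#' minimum RMSECV is returned.  The PLS component count is re-chosen by
#' internal CV at every step.
#'
#' @param X,y Calibration spectra and reference values.
#' @param n_iterations Monte-Carlo iterations (default 50).
#' @param mc_fraction Fraction of samples drawn per iteration.
#' @param cv_folds Folds for the RMSECV trace.
#' @param max_pls_components Upper bound for the internal component choice.
#' @param seed Integer seed; the run is fully deterministic given it.
#' @return A `selection_result` with fields `selected`, `rmsecv_trace`,
#'   `retained_counts`, `best_iteration`, `seed`.
#' @export
cars_select <- function(X, y, n_iterations = 50, mc_fraction = 0.8,
                        cv_folds = 5, max_pls_components = 10, seed = 1) {
  X <- validate_selection_input(X, y, cv_folds)
  if (mc_fraction <= 0 || mc_fraction >= 1) stop_invalid("mc_fraction must be in (0,1)")
  if (n_iterations < 2) stop_invalid("n_iterations must be >= 2")
  n <- nrow(X); p <- ncol(X)
  if (p <= 2) stop_invalid("need more than 2 variables")

  with_seed(seed, {
    fold_id <- make_folds(n, cv_folds, seed = seed + 1L)
    pool <- seq_len(p)
    rmsecv <- numeric(n_iterations)
    counts <- integer(n_iterations)
    sets <- vector("list", n_iterations)
    n_sub <- max(2L, ceiling(mc_fraction * n))
    for (i in seq_len(n_iterations)) {
      sub <- sample.int(n, n_sub)
      Xs <- X[sub, pool, drop = FALSE]
      k <- choose_pls_components(Xs, y[sub],
                                 min(max_pls_components, length(pool)),
                                 cv_folds)
      b <- abs(fit_pls(Xs, y[sub], k)$coefficients)
      forced <- min(ceiling(edf_retention_ratio(i, n_iterations, p) * p),
                    length(pool))
      forced <- max(forced, 2L)
      ord <- order(-b, pool)              # ties -> lowest variable index
      keep <- pool[ord[seq_len(forced)]]
      w <- b[ord[seq_len(forced)]]
      if (all(w == 0)) w <- rep(1, length(w))
      drawn <- unique(sample(keep, size = forced, replace = TRUE, prob = w))
      if (length(drawn) < 2L) drawn <- unique(c(drawn, keep))[1:2]
      pool <- sort(drawn)
      sets[[i]] <- pool
      counts[i] <- length(pool)
      rmsecv[i] <- min(pls_cv_rmse(X[, pool, drop = FALSE], y,
                                   min(max_pls_components, length(pool)),
                                   cv_folds, fold_id))
    }
    best <- which.min(rmsecv)
    new_selection_result("CARS", sets[[best]], seed,
                         rmsecv_trace = rmsecv, retained_counts = counts,
                         best_iteration = best)
  })
}

#' Uninformative variable elimination (UVE)
#'
#' Appends `p` random noise variables of amplitude `noise_amplitude` to the
#' spectra, collects PLS coefficient vectors over leave-one-out resampling
#' (or a 10-fold jackknife when `n > 150`), and computes each variable's
#' reliability \eqn{c_j = \mathrm{mean}(b_j)/\mathrm{sd}(b_j)}.  Real
#' variables whose |reliability| exceeds `cutoff_factor` times the largest
#' |reliability| among the noise variables are retained -- by construction a
#' noise variable can never be selected.
#'
#' @param X,y Calibration data.
#' @param noise_amplitude Scale of the appended noise columns.
#' @param cutoff_factor Multiplier on the noise reliability maximum.
#' @param max_pls_components Bound for the component count, chosen once by
#'   CV on the real variables.
#' @param loo_threshold Sample size above which the jackknife switches from
#'   leave-one-out to 10 folds.
#' @param seed Integer seed.
#' @return A `selection_result` with fields `selected`, `reliability`
#'   (length `2p`: real then noise variables), `cutoff`, `n_components`.
#' @export
uve_select <- function(X, y, noise_amplitude = 1e-10, cutoff_factor = 1,
                       max_pls_components = 10, loo_threshold = 150, seed = 1) {
  X <- validate_selection_input(X, y, 2)
  if (noise_amplitude <= 0) stop_invalid("noise_amplitude must be > 0")
  if (cutoff_factor <= 0) stop_invalid("cutoff_factor must be > 0")
  n <- nrow(X); p <- ncol(X)
  with_seed(seed, {
    noise <- matrix(stats::rnorm(n * p), n, p) * noise_amplitude
    Xa <- cbind(X, noise)
    k <- choose_pls_components(X, y, min(max_pls_components, p, n - 3), 5)
    fold_id <- if (n <= loo_threshold) seq_len(n) else make_folds(n, 10, seed = seed + 1L)
    folds <- sort(unique(fold_id))
    Bmat <- matrix(0, length(folds), 2L * p)
    for (fi in seq_along(folds)) {
      tr <- fold_id != folds[fi]
      Bmat[fi, ] <- fit_pls(Xa[tr, , drop = FALSE], y[tr], k)$coefficients
    }
    mu <- colMeans(Bmat)
    sdv <- apply(Bmat, 2, stats::sd)
    rel <- mu / sdv
    zero_sd <- sdv == 0
    if (any(zero_sd[seq_len(p)])) {
      warning("zero coefficient spread for some real variables; retained with infinite reliability",
              call. = FALSE)
      rel[seq_len(p)][zero_sd[seq_len(p)]] <- Inf
    }
    rel[!is.finite(rel) & zero_sd & mu == 0] <- 0
    noise_rel <- abs(rel[p + seq_len(p)])
    cutoff <- cutoff_factor * max(noise_rel[is.finite(noise_rel)], 0)
    selected <- which(abs(rel[seq_len(p)]) > cutoff)
    new_selection_result("UVE", selected, seed,
                         reliability = rel, cutoff = cutoff, n_components = k)
  })
}

#' Genetic-algorithm wavelength selection
#'
#' Binary chromosomes of length `p` encode variable subsets; fitness is the
#' negative cross-validated PLS RMSE of the active subset (component count
#' optimized within `max_pls_components`).  Tournament selection, uniform
#' crossover, bit-flip mutation and elitism evolve the population; the
#' whole search is repeated `n_runs` times with distinct sub-seeds, and
#' variables selected in at least `frequency_threshold * n_runs` of the
#' run-best chromosomes are returned.  Empty chromosomes get worst fitness.
#'
#' @param X,y Calibration data.
#' @param population_size,n_generations,crossover_rate,mutation_rate,elitism
#'   GA controls.
#' @param n_runs Independent repetitions.
#' @param frequency_threshold Fraction of runs a variable must appear in.
#' @param fitness_cv_folds CV folds inside the fitness function.
#' @param max_pls_components Bound for the component choice.
#' @param init_prob Per-gene activation probability at initialization.
#' @param seed Integer seed; run `r` uses sub-seed `seed + 7919 * r`.
#' @return A `selection_result` with fields `selected`, `frequency`
#'   (per-variable counts over run-best chromosomes) and
#'   `best_fitness_traces` (one non-decreasing vector per run).
#' @export
ga_select <- function(X, y, population_size = 64, n_generations = 100,
                      crossover_rate = 0.5, mutation_rate = 0.01,
                      n_runs = 5, frequency_threshold = 3 / 5,
                      fitness_cv_folds = 5, max_pls_components = 10,
                      elitism = 1, init_prob = 0.1, seed = 1) {
  X <- validate_selection_input(X, y, fitness_cv_folds)
  if (population_size < 2) stop_invalid("population_size must be >= 2")
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1) {
    stop_invalid("rates must lie in [0, 1]")
  }
  n <- nrow(X); p <- ncol(X)

  best_chroms <- matrix(FALSE, n_runs, p)
  traces <- vector("list", n_runs)
  cache <- new.env(parent = emptyenv())
  # one fold assignment shared by all runs: fitness values are comparable
  # across runs and cacheable by chromosome alone
  fold_id <- make_folds(n, fitness_cv_folds, seed = seed)
  for (r in seq_len(n_runs)) {
    run <- with_seed(seed + 7919L * r, {
      fitness <- function(chrom) {
        active <- which(chrom)
        if (!length(active)) return(-Inf)
        key <- paste(active, collapse = ",")
        hit <- cache[[key]]
        if (!is.null(hit)) return(hit)
        val <- -min(pls_cv_rmse(X[, active, drop = FALSE], y,
                                min(max_pls_components, length(active)),
                                fitness_cv_folds, fold_id))
        cache[[key]] <- val
        val
      }
      pop <- matrix(stats::runif(population_size * p) < init_prob,
                    population_size, p)
      empty <- rowSums(pop) == 0
      for (i in which(empty)) pop[i, sample.int(p, 1)] <- TRUE
      trace <- numeric(n_generations)
      fit <- apply(pop, 1, fitness)
      for (g in seq_len(n_generations)) {
        ord <- order(-fit)
        trace[g] <- fit[ord[1]]
        newpop <- matrix(FALSE, population_size, p)
        n_elite <- min(elitism, population_size - 1L)
        newpop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], , drop = FALSE]
        for (i in seq(n_elite + 1, population_size)) {
          pick <- function() {
            cand <- sample.int(population_size, 2)
            cand[which.max(fit[cand])]
          }
          p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
          child <- if (stats::runif(1) < crossover_rate) {
            mask <- stats::runif(p) < 0.5
            ifelse(mask, p1, p2)
          } else p1
          flip <- stats::runif(p) < mutation_rate
          newpop[i, ] <- xor(child, flip)
        }
        pop <- newpop
        fit <- apply(pop, 1, fitness)
      }
      ord <- order(-fit)
      list(best = pop[ord[1], ], trace = trace, best_fit = fit[ord[1]])
    })
    best_chroms[r, ] <- run$best
    traces[[r]] <- run$trace
  }
  freq <- colSums(best_chroms)
  selected <- which(freq >= frequency_threshold * n_runs)
  if (!length(selected)) {
    warning("no variable reached the frequency threshold; falling back to the best single run",
            call. = FALSE)
    best_run <- which.max(vapply(traces, function(t) t[length(t)], numeric(1)))
    selected <- which(best_chroms[best_run, ])
  }
  new_selection_result("GA", selected, seed,
                       frequency = freq, best_fitness_traces = traces,
                       frequency_threshold = frequency_threshold, n_runs = n_runs)
}

#' Hypergeometric enrichment of a selection in a wavenumber band
#'
#' Tail probability of observing at least the realized number of selected
#' variables inside `band`, given the band size, the grid size and the
#' selection size (draws without replacement).  Used to check that selected
#' wavelengths concentrate in chemically meaningful Raman regions.
#'
#' @param result A `selection_result` (or an integer vector of indices).
#' @param band Length-2 wavenumber interval `c(lo, hi)` in cm\eqn{^{-1}}.
#' @param wavenumbers The grid the selection indexes into.
#' @return Upper-tail hypergeometric p-value.
#' @export
selection_enrichment <- function(result, band, wavenumbers) {
  selected <- if (inherits(result, "selection_result")) result$selected else result
  if (!length(selected)) stop_invalid("empty selection")
  if (length(band) != 2 || band[1] > band[2]) stop_invalid("band must be c(lo, hi)")
  if (band[2] < min(wavenumbers) || band[1] > max(wavenumbers)) {
    stop_invalid("band [%g, %g] lies outside the grid [%g, %g]",
                 band[1], band[2], min(wavenumbers), max(wavenumbers))
  }
  p_total <- length(wavenumbers)
  in_band <- which(wavenumbers >= band[1] & wavenumbers <= band[2])
  K <- length(in_band)
  k <- sum(selected %in% in_band)
  stats::phyper(k - 1, K, p_total - K, length(selected), lower.tail = FALSE)
}
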