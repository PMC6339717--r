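#' Simulate a dissolution profile from a known model
#'
#' Generates `Q_i = f(t_i) + eps_i` with `f` one of the six release models
#' and `eps_i` independent Gaussian noise with per-point standard deviation
#' `sigma`, mirroring the structure of the packaged profiles (monotone
#' trend, symmetric error bars of a few percent). The generated dataset
#' carries `sigma` as its error bars, so the chi-square machinery sees the
#' true noise scale — at the true parameters the statistic then has mean
#' `N`, which the test suite uses as a direct check of the weighting.
#'
#' Clipping to \[0, 100\] is available but off by default: truncation breaks
#' the Gaussian error model that the chi-square objective assumes, so
#' calibration experiments run unclipped.
#'
#' @param model_id Model identifier (see [kinetic_models()]).
#' @param params Named true parameter vector.
#' @param times Strictly increasing sampling times, `>= 0`.
#' @param sigma Noise standard deviation(s) in percent: scalar or one value
#'   per time point.
#' @param time_unit `"hour"` or `"day"`.
#' @param label Dataset label.
#' @param clip If `TRUE`, clip simulated values into \[0, 100\] (clipped
#'   rows are recorded in the `clipped` attribute).
#' @param seed Optional integer; if given, the RNG state is set locally and
#'   restored on exit, making the draw reproducible without touching the
#'   caller's stream.
#' @return A [release_dataset()] with attribute `truth` (list of `model_id`
#'   and `params`).
#' @examples
#' ds <- simulate_release("power_law", c(A = 23.36, n = 0.2856),
#'                        times = c(1, 2, 4, 8, 24, 48), sigma = 2, seed = 1)
#' @export
simulate_release <- function(model_id, params, times, sigma,
                             time_unit = c("hour", "day"), label = "simulated",
                             clip = FALSE, seed = NULL) {
  time_unit <- match.arg(time_unit)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  n <- length(times)
  sigma <- rep_len(sigma, n)
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  mu <- evaluate_model(model_id, params, times)
  q <- mu + stats::rnorm(n, 0, sigma)
  clipped <- logical(n)
  if (clip) {
    clipped <- q < 0 | q > 100
    q <- pmin(pmax(q, 0), 100)
  }
  ds <- suppressWarnings(
    release_dataset(times, q, sigma, time_unit = time_unit, label = label))
  attr(ds, "truth") <- list(model_id = model_spec(model_id)$model_id,
                            params = params)
  attr(ds, "clipped") <- clipped
  ds
}

#' Parameter-recovery and selection-consistency experiment
#'
#' Repeatedly simulates profiles from a known model, runs the full
#' model-comparison pipeline on each replicate, and summarizes (i) how often
#' each model is selected as best and (ii) bias and RMSE of the fitted
#' parameters of the true model. The whole experiment is deterministic for a
#' fixed `seed`. Replicates whose true-model fit fails are recorded and
#' skipped in the parameter summaries, never fatal.
#'
#' @param model_id True model identifier.
#' @param params True parameter vector.
#' @param times,sigma Sampling grid and noise levels, as in
#'   [simulate_release()].
#' @param n_reps Number of replicates, `>= 2`.
#' @param seed Integer seed for the experiment stream.
#' @param config A [fit_config()] for the fits.
#' @return A list of class `recovery_summary`: `selection` (named selection
#'   frequencies), `estimates` (one row per replicate: best model, fitted
#'   true-model parameters, chi-square at the truth), `bias`, `rmse`, and
#'   `n_failed`.
#' @examples
#' recovery_experiment("higuchi", c(k = 10), times = c(1, 2, 4, 8, 16),
#'                     sigma = 1, n_reps = 5, seed = 1)
#' @export
recovery_experiment <- function(model_id, params, times, sigma, n_reps, seed,
                                config = fit_config()) {
  stopifnot(n_reps >= 2)
  spec <- model_spec(model_id)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    ds <- simulate_release(spec$model_id, params, times, sigma)
    chi2_truth <- chi2_stat(spec, params, ds)
    cmp <- compare_models(ds, config)
    fit <- Filter(function(f) f$model_id == spec$model_id, cmp$fits)[[1L]]
    est <- if (fit$converged) fit$params else
      stats::setNames(rep(NA_real_, spec$m), spec$param_names)
    rows[[r]] <- data.frame(rep = r, best_model = cmp$best_model,
                            as.list(stats::setNames(est, spec$param_names)),
                            chi2_at_truth = chi2_truth,
                            failed = !fit$converged)
  }
  est <- do.call(rbind, rows)
  ok <- !est$failed
  truth <- params[spec$param_names]
  bias <- colMeans(est[ok, spec$param_names, drop = FALSE]) - truth
  rmse <- sqrt(colMeans(
    (est[ok, spec$param_names, drop = FALSE] -
       matrix(truth, sum(ok), spec$m, byrow = TRUE))^2))
  selection <- table(factor(est$best_model, levels = kinetic_models())) / n_reps
  structure(list(model_id = spec$model_id, truth = truth,
                 selection = c(selection), estimates = est,
                 bias = bias, rmse = rmse,
                 mean_chi2_at_truth = mean(est$chi2_at_truth),
                 n_reps = n_reps, n_failed = sum(!ok)),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat("Recovery experiment: truth =", x$model_id, "(",
      paste(names(x$truth), "=", format(x$truth, digits = 5), collapse = ", "),
      "),", x$n_reps, "replicates\n")
  cat("  selected best:",
      paste(names(x$selection)[x$selection > 0], "=",
            format(x$selection[x$selection > 0], digits = 3), collapse = ", "),
      "\n")
  cat("  bias:", paste(names(x$bias), "=", format(x$bias, digits = 4),
                       collapse = ", "), "\n")
  cat("  rmse:", paste(names(x$rmse), "=", format(x$rmse, digits = 4),
                       collapse = ", "), "\n")
  cat("  mean chi2 at truth:", format(x$mean_chi2_at_truth, digits = 5), "\n")
  if (x$n_failed) cat(" ", x$n_failed, "replicate(s) failed to converge\n")
  invisible(x)
}

#' Sampling grids of the packaged profiles
#'
#' Convenience accessors for the two time grids the packaged datasets use:
#' `"lnp"` (10 points over 1--48 h, the liposomal-nanoparticle profiles) and
#' `"plga"` (12 points over 1--30 d). Useful as defaults for simulation
#' experiments that should mirror the real sampling designs.
#'
#' @param grid `"lnp"` or `"plga"`.
#' @return List with `times`, `sigma` (the error bars of the corresponding
#'   packaged dataset) and `time_unit`.
#' @export
fixture_grid <- function(grid = c("lnp", "plga")) {
  grid <- match.arg(grid)
  ds <- load_fixture(switch(grid, lnp = "dox", plga = "plga"))
  list(times = ds$time, sigma = ds$error, time_unit = time_unit(ds))
}
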