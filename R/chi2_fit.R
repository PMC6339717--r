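#' Weighted chi-square of a model against a dissolution profile
#'
#' The objective minimized throughout the package:
#' \deqn{\chi^2(a_1,\dots,a_m) = \sum_{i=1}^{N}
#'   \frac{(f(t_i; a_1,\dots,a_m) - Q_i)^2}{\sigma_i^2},}
#' summing over every experimental time point, where \eqn{f} is the model
#' curve, \eqn{Q_i} the measured dissolution and \eqn{\sigma_i} the per-point
#' error bar. Under independent Gaussian noise with known standard deviations
#' \eqn{\sigma_i}, this is the standard chi-square statistic, with
#' \eqn{E[\chi^2] = N} at the true parameters.
#'
#' @param model_id Model identifier or spec (see [kinetic_models()]).
#' @param params Named numeric parameter vector.
#' @param ds A [release_dataset()].
#' @return The non-negative chi-square value.
#' @examples
#' ds <- load_fixture("dox")
#' chi2_stat("higuchi", c(k = 10.6865), ds)
#' @export
chi2_stat <- function(model_id, params, ds) {
  stopifnot(inherits(ds, "release_dataset"))
  if (any(ds$error == 0)) stop("zero error bar: chi-square undefined", call. = FALSE)
  pred <- evaluate_model(model_id, params, ds$time)
  sum(((pred - ds$dissolution_percent) / ds$error)^2)
}

#' Fitting configuration
#'
#' Controls the deterministic multi-start nonlinear minimization used by
#' [fit_nonlinear()]. The start grid is `grid_size` x `grid_size` points,
#' log-spaced over a factor of `span` around a regression-based initial
#' guess (see [fit_nonlinear()] for the per-model regressions).
#'
#' @param grid_size Points per parameter axis of the start grid (odd keeps
#'   the regression guess itself on the grid).
#' @param span Multiplicative half-width of the start grid.
#' @param ftol,ptol Relative tolerances on the chi-square decrease and the
#'   parameter step at convergence. Defaults give parameter values stable to
#'   well past the 4 decimals used in reports.
#' @param maxit Maximum iterations per start.
#' @param bounds Optional named list overriding the default parameter boxes,
#'   e.g. `list(power_law = list(lower = c(A = 0, n = 0), upper = c(A = Inf,
#'   n = 2)))`. Defaults: `A`, `k`, `Q0` positive; `n` in (0, 2];
#'   `zero_order` and `hixson_crowell` coefficients unbounded.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(grid_size = 5L, span = 10, ftol = 1e-12, ptol = 1e-12,
                       maxit = 1024L, bounds = NULL) {
  stopifnot(grid_size >= 1L, span > 1, ftol > 0, ptol > 0, maxit >= 1L)
  structure(list(grid_size = as.integer(grid_size), span = span,
                 ftol = ftol, ptol = ptol, maxit = as.integer(maxit),
                 bounds = bounds),
            class = "fit_config")
}

.default_bounds <- list(
  power_law      = list(lower = c(A = 1e-12, n = 1e-12), upper = c(A = Inf, n = 2)),
  first_order    = list(lower = c(Q0 = 1e-12, k = -Inf), upper = c(Q0 = Inf, k = Inf)),
  hixson_crowell = list(lower = c(A = -Inf, B = -Inf),   upper = c(A = Inf, B = Inf)),
  zero_order     = list(lower = c(A = -Inf, B = -Inf),   upper = c(A = Inf, B = Inf)),
  higuchi        = list(lower = c(k = 1e-12), upper = c(k = Inf)),
  hopfenberg     = list(lower = c(k = 1e-12), upper = c(k = Inf))
)

.model_bounds <- function(model_id, config) {
  b <- config$bounds[[model_id]]
  if (is.null(b)) b <- .default_bounds[[model_id]]
  b
}

.new_fit <- function(spec, params, chi2_min, ds, converged, n_starts_used) {
  N <- nrow(ds)
  dof <- N - spec$m
  w <- 1 / ds$error^2
  qbar <- sum(w * ds$dissolution_percent) / sum(w)
  chi2_null <- sum(w * (ds$dissolution_percent - qbar)^2)
  r2 <- 1 - chi2_min / chi2_null
  structure(list(
    model_id = spec$model_id, label = spec$label, m = spec$m,
    params = params, chi2_min = chi2_min, dof = dof,
    chi2_per_dof = chi2_min / dof,
    r2 = r2, r2_adjusted = r2_adjusted(r2, N, spec$m),
    converged = converged, n_starts_used = n_starts_used, N = N
  ), class = "release_fit")
}

#' @export
print.release_fit <- function(x, ...) {
  cat(x$label, " fit (m = ", x$m, "): ",
      paste(names(x$params), "=", format(x$params, digits = 6), collapse = ", "),
      "\n  chi2_min = ", format(x$chi2_min, digits = 6),
      ", d.o.f. = ", x$dof,
      ", chi2/d.o.f. = ", format(x$chi2_per_dof, digits = 6),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

#' Exact weighted least squares for the linear-in-parameters models
#'
#' `zero_order`, `higuchi` and `hopfenberg` are linear in their parameters
#' (bases \{1, t\}, \{sqrt(t)\} and \{t\}), so the chi-square minimum is the
#' solution of the weighted normal equations and is global and closed-form.
#'
#' @param model_id One of `"zero_order"`, `"higuchi"`, `"hopfenberg"`.
#' @param ds A [release_dataset()] with more points than parameters.
#' @return A `release_fit`: best-fit parameters, `chi2_min`, `dof = N - m`,
#'   `chi2_per_dof`, weighted `r2` and `r2_adjusted`.
#' @examples
#' fit_linear("higuchi", load_fixture("dox"))
#' @export
fit_linear <- function(model_id, ds) {
  spec <- model_spec(model_id)
  if (!isTRUE(spec$linear_in_params)) {
    stop(spec$model_id, " is not linear in its parameters", call. = FALSE)
  }
  stopifnot(inherits(ds, "release_dataset"))
  if (nrow(ds) <= spec$m) stop("need N > m data points", call. = FALSE)
  X <- spec$basis(ds$time)
  w <- 1 / ds$error^2
  qr_ok <- qr(sqrt(w) * X)
  if (qr_ok$rank < ncol(X)) {
    stop("degenerate design: singular normal equations for ", spec$model_id,
         call. = FALSE)
  }
  fit <- stats::lm.wfit(X, ds$dissolution_percent, w)
  params <- stats::setNames(fit$coefficients, spec$param_names)
  chi2_min <- sum(w * fit$residuals^2)
  .new_fit(spec, params, chi2_min, ds, converged = TRUE, n_starts_used = 0L)
}

.start_points <- function(model_id, ds, config) {
  t <- ds$time; Q <- ds$dissolution_percent; w <- 1 / ds$error^2
  base <- switch(model_id,
    power_law = {
      ok <- t > 0 & Q > 0
      if (sum(ok) >= 2) {
        co <- stats::lm.wfit(cbind(1, log(t[ok])), log(Q[ok]), w[ok])$coefficients
        c(A = unname(exp(co[1])), n = unname(min(max(co[2], 0.05), 2)))
      } else c(A = max(Q[Q > 0], 1), n = 0.5)
    },
    first_order = {
      ok <- Q > 0
      co <- stats::lm.wfit(cbind(1, t[ok]), log(Q[ok]), w[ok])$coefficients
      c(Q0 = unname(exp(co[1])), k = unname(co[2] * 2.303))
    },
    hixson_crowell = {
      ok <- Q >= 0
      co <- stats::lm.wfit(cbind(1, t[ok]), Q[ok]^(1 / 3), w[ok])$coefficients
      c(A = unname(co[1]), B = unname(co[2]))
    },
    stop("no start rule for ", model_id, call. = FALSE)
  )
  g <- config$grid_size
  fac <- exp(seq(-log(config$span), log(config$span), length.out = g))
  perturb <- function(v) {
    out <- if (abs(v) > 1e-8) v * fac else v + (fac - 1) * 0.01
    sort(unique(out))
  }
  grid <- expand.grid(perturb(base[1]), perturb(base[2]), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- names(base)
  # regression guess first so n_starts_used = 1 on easy problems
  starts <- rbind(as.data.frame(as.list(base)), grid)
  b <- .model_bounds(model_id, config)
  for (j in seq_along(starts)) {
    v <- starts[[j]]
    if (is.finite(b$lower[j])) v <- pmax(v, b$lower[j] + 1e-12)
    if (is.finite(b$upper[j])) v <- pmin(v, b$upper[j])
    starts[[j]] <- v
  }
  unique(starts)
}

#' Multi-start nonlinear chi-square minimization
#'
#' Minimizes [chi2_stat()] over the model's parameter box by
#' Levenberg--Marquardt on the sigma-scaled residuals
#' (via [minpack.lm::nls.lm()]), launched from a deterministic set of starts:
#' a weighted-regression initial guess (log--log regression for the power
#' law, log-linear for first order, cube-root-affine for Hixson--Crowell)
#' plus a log-spaced grid around it (see [fit_config()]). The best local
#' minimum across starts is returned; determinism of the start set makes the
#' result reproducible run-to-run. Linear models are delegated to
#' [fit_linear()].
#'
#' @param model_id Model identifier (see [kinetic_models()]).
#' @param ds A [release_dataset()] with more points than parameters.
#' @param config A [fit_config()].
#' @return A `release_fit` (see [fit_linear()]); `converged` is `FALSE` only
#'   if no start converged, in which case the best point found is still
#'   reported.
#' @examples
#' fit_nonlinear("power_law", load_fixture("dox"))
#' @export
fit_nonlinear <- function(model_id, ds, config = fit_config()) {
  spec <- model_spec(model_id)
  if (isTRUE(spec$linear_in_params)) return(fit_linear(spec, ds))
  stopifnot(inherits(ds, "release_dataset"))
  if (nrow(ds) <= spec$m) stop("need N > m data points", call. = FALSE)
  b <- .model_bounds(spec$model_id, config)
  if (length(b$lower) != spec$m || length(b$upper) != spec$m ||
      any(b$lower > b$upper)) {
    stop("invalid parameter box for ", spec$model_id, call. = FALSE)
  }
  resid_fn <- function(p) {
    p <- stats::setNames(p, spec$param_names)
    (evaluate_model(spec, p, ds$time) - ds$dissolution_percent) / ds$error
  }
  starts <- .start_points(spec$model_id, ds, config)
  ctrl <- minpack.lm::nls.lm.control(ftol = config$ftol, ptol = config$ptol,
                                     maxiter = min(config$maxit, 1024L))
  best <- NULL; best_chi2 <- Inf; any_conv <- FALSE; used <- 0L
  for (i in seq_len(nrow(starts))) {
    used <- used + 1L
    res <- tryCatch(
      minpack.lm::nls.lm(par = as.numeric(starts[i, ]), fn = resid_fn,
                         lower = b$lower, upper = b$upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$deviance)) next
    any_conv <- any_conv || res$info %in% 1:4
    if (res$deviance < best_chi2) {
      best_chi2 <- res$deviance
      best <- res
    }
  }
  if (is.null(best)) stop("all starts failed for ", spec$model_id, call. = FALSE)
  params <- stats::setNames(best$par, spec$param_names)
  .new_fit(spec, params, best$deviance, ds, converged = any_conv,
           n_starts_used = used)
}

#' Fit one model to a dissolution profile
#'
#' Dispatches to the closed-form weighted least squares for
#' linear-in-parameters models and to the multi-start minimizer otherwise.
#'
#' @inheritParams fit_nonlinear
#' @return A `release_fit`.
#' @examples
#' fit_model("power_law", load_fixture("dox"))
#' @export
fit_model <- function(model_id, ds, config = fit_config()) {
  spec <- model_spec(model_id)
  if (isTRUE(spec$linear_in_params)) fit_linear(spec, ds)
  else fit_nonlinear(spec, ds, config)
}

#' Adjusted coefficient of determination
#'
#' \deqn{R^2_{adj} = 1 - (1 - R^2)\,\frac{N - 1}{N - m}.}
#' Penalizes \eqn{R^2} for the number of free parameters; reported alongside
#' chi-square per degree of freedom so the two selection statistics can be
#' contrasted (they can disagree — the package ranks by chi-square per
#' degree of freedom only).
#'
#' @param r2 Coefficient of determination.
#' @param N Number of data points.
#' @param m Number of free parameters, with `N > m >= 1`.
#' @return The adjusted value.
#' @examples
#' r2_adjusted(0.9, N = 10, m = 2)
#' @export
r2_adjusted <- function(r2, N, m) {
  if (m < 1 || N <= m) stop("need N > m >= 1", call. = FALSE)
  1 - (1 - r2) * (N - 1) / (N - m)
}
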