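# Independent grid-search oracle for the chi-square minima.
#
# Certifies the optimizer route: exhaustive evaluation of chi2 on a crude
# data-derived bounding box (never taken from the fitted values), keeping the
# best cell and shrinking the box around it on each refinement pass.

oracle_box <- function(model_id, ds) {
  qmax <- max(ds$dissolution_percent)
  tmax <- max(ds$time)
  switch(model_id,
    higuchi        = list(lower = c(k = 1e-3), upper = c(k = 3 * qmax / sqrt(tmax))),
    hopfenberg     = list(lower = c(k = 1e-3), upper = c(k = 3 * qmax / tmax)),
    zero_order     = list(lower = c(A = -qmax, B = -2 * qmax / tmax),
                          upper = c(A = 2 * qmax, B = 3 * qmax / tmax)),
    power_law      = list(lower = c(A = 1e-3, n = 1e-3),
                          upper = c(A = 2 * qmax, n = 2)),
    first_order    = list(lower = c(Q0 = 1e-3, k = -1),
                          upper = c(Q0 = 2 * qmax, k = 1)),
    hixson_crowell = list(lower = c(A = -2, B = -2 * qmax^(1 / 3) / tmax),
                          upper = c(A = 1.5 * qmax^(1 / 3),
                                    B = 3 * qmax^(1 / 3) / tmax)))
}

grid_search_chi2 <- function(model_id, ds, n_grid = 61L, n_refine = 4L) {
  spec <- model_spec(model_id)
  box <- oracle_box(spec$model_id, ds)
  Q <- ds$dissolution_percent
  w <- 1 / ds$error^2
  chi2_of <- function(pv) {
    pred <- evaluate_model(spec, stats::setNames(pv, spec$param_names), ds$time)
    sum((pred - Q)^2 * w)
  }
  lower <- box$lower; upper <- box$upper
  m <- spec$m
  best <- NULL
  for (stage in seq_len(n_refine + 1L)) {
    axes <- lapply(seq_len(m), function(j) seq(lower[j], upper[j], length.out = n_grid))
    grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
    vals <- apply(grid, 1L, chi2_of)
    i <- which.min(vals)
    best <- list(params = stats::setNames(grid[i, ], spec$param_names),
                 chi2 = vals[i])
    # shrink to +-3 cells around the best point; wide enough that a narrow
    # curved valley (first-order's correlated Q0-k trough) stays inside
    for (j in seq_len(m)) {
      h <- 3 * (upper[j] - lower[j]) / (n_grid - 1L)
      lower[j] <- max(box$lower[j], best$params[j] - h)
      upper[j] <- min(box$upper[j], best$params[j] + h)
    }
  }
  best
}
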