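dox <- load_fixture("dox")

test_that("chi-square sums sigma-scaled squared residuals over all points", {
  # point 1: prediction 12 vs Q = 10, sigma = 2 -> term (12-10)^2/4 = 1;
  # point 2 fits exactly -> total chi2 = 1
  ds <- release_dataset(c(1, 2), c(10, 12), c(2, 1))
  expect_equal(chi2_stat("zero_order", c(A = 12, B = 0), ds), 1)
  # perfect fit -> 0
  t <- c(1, 4, 9)
  ds2 <- release_dataset(t, 3 * sqrt(t), c(1, 2, 1))
  expect_equal(chi2_stat("higuchi", c(k = 3), ds2), 0)
  # hand-summed value on a real profile
  by_hand <- sum((10.6865 * sqrt(dox$time) - dox$dissolution_percent)^2 / dox$error^2)
  expect_equal(chi2_stat("higuchi", c(k = 10.6865), dox), by_hand)
  expect_equal(by_hand / 9, 13.1467, tolerance = 1e-4)
})

test_that("closed-form weighted least squares matches lm() on the linear models", {
  w <- 1 / dox$error^2
  for (id in c("zero_order", "higuchi", "hopfenberg")) {
    fit <- fit_linear(id, dox)
    X <- model_spec(id)$basis(dox$time)
    ref <- lm(dox$dissolution_percent ~ X - 1, weights = w)
    expect_equal(unname(fit$params), unname(coef(ref)), tolerance = 1e-10,
                 label = id)
    expect_equal(fit$chi2_min, sum(w * resid(ref)^2), tolerance = 1e-10)
    expect_equal(fit$chi2_per_dof, fit$chi2_min / fit$dof)
    expect_equal(fit$dof, nrow(dox) - model_spec(id)$m)
  }
  expect_error(fit_linear("power_law", dox), "not linear")
})

test_that("multi-start minimizer matches direct optim() on the dox profile", {
  for (id in c("power_law", "first_order", "hixson_crowell")) {
    fit <- fit_nonlinear(id, dox)
    expect_true(fit$converged)
    spec <- model_spec(id)
    obj <- function(p) chi2_stat(spec, setNames(p, spec$param_names), dox)
    ref <- optim(unname(fit$params) * 1.3, obj,
                 control = list(reltol = 1e-15, maxit = 20000))
    ref <- optim(ref$par, obj, method = "BFGS", control = list(reltol = 1e-14))
    expect_lte(fit$chi2_min, ref$value * (1 + 1e-6))
    expect_equal(fit$chi2_min, ref$value, tolerance = 1e-5, label = id)
  }
})

test_that("chi-square is invariant under joint rescaling of Q, sigma, prediction", {
  c0 <- 3.7
  scaled <- suppressWarnings(  # scaled values legitimately exceed 100 %
    release_dataset(dox$time, c0 * dox$dissolution_percent, c0 * dox$error))
  expect_equal(chi2_stat("higuchi", c(k = c0 * 10.6865), scaled),
               chi2_stat("higuchi", c(k = 10.6865), dox))
  expect_equal(fit_linear("higuchi", scaled)$chi2_min,
               fit_linear("higuchi", dox)$chi2_min)
})

test_that("adding parameters never hurts nested models on any fixture", {
  for (nm in c("dox", "mtx", "plga", "ca_plga", "pd_pcl_nc")) {
    ds <- load_fixture(nm)
    hop <- fit_model("hopfenberg", ds)$chi2_min
    hig <- fit_model("higuchi", ds)$chi2_min
    pw <- fit_model("power_law", ds)$chi2_min
    zo <- fit_model("zero_order", ds)$chi2_min
    expect_lte(pw, hig * (1 + 1e-9), label = paste(nm, "higuchi in power_law"))
    expect_lte(pw, hop * (1 + 1e-9), label = paste(nm, "hopfenberg in power_law"))
    expect_lte(zo, hop * (1 + 1e-9), label = paste(nm, "hopfenberg in zero_order"))
  }
})

test_that("fits refuse datasets without degrees of freedom", {
  ds <- release_dataset(c(1, 2), c(10, 20), c(1, 1))
  expect_error(fit_linear("zero_order", ds), "N > m")
  expect_error(fit_nonlinear("power_law", ds), "N > m")
  expect_silent(fit_linear("higuchi", ds))  # m = 1, dof = 1
})

test_that("adjusted R-squared follows the parameter-count penalty", {
  expect_equal(r2_adjusted(1, 10, 2), 1)
  expect_equal(r2_adjusted(0.9, 10, 2), 1 - 0.1 * 9 / 8)
  expect_equal(r2_adjusted(0.9, 10, 1), 0.9)
  expect_error(r2_adjusted(0.9, 2, 2), "N > m")
})

test_that("fit results expose weighted R-squared consistent with the null model", {
  fit <- fit_linear("higuchi", dox)
  w <- 1 / dox$error^2
  qbar <- sum(w * dox$dissolution_percent) / sum(w)
  chi2_null <- sum(w * (dox$dissolution_percent - qbar)^2)
  expect_equal(fit$r2, 1 - fit$chi2_min / chi2_null)
  expect_equal(fit$r2_adjusted, r2_adjusted(fit$r2, fit$N, fit$m))
})
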