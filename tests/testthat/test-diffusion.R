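erfc_ref <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)

test_that("repeated erfc integral matches its closed forms at the origin", {
  expect_equal(inerfc(0, 0), 1)
  expect_equal(inerfc(1, 0), 1 / sqrt(pi), tolerance = 1e-10)
  for (nu in c(-0.5, 0.2856 * 2, 1.5, 3)) {
    expect_equal(inerfc(nu, 0), 2^(-nu) / gamma(nu / 2 + 1),
                 tolerance = 1e-9, label = paste("nu =", nu))
  }
  expect_error(inerfc(-1, 1), "exceed -1")
  expect_error(inerfc(0, -0.5), "non-negative")
})

test_that("order zero reduces to erfc and integer orders obey the recurrence", {
  x <- c(0, 0.3, 1, 2.2)
  expect_equal(inerfc(0, x), erfc_ref(x), tolerance = 1e-10)
  # classical recurrence i^nu = -x/nu * i^(nu-1) + 1/(2 nu) * i^(nu-2),
  # seeded by i^-1 = 2/sqrt(pi) exp(-x^2) and i^0 = erfc
  prev2 <- 2 / sqrt(pi) * exp(-x^2)
  prev1 <- erfc_ref(x)
  for (nu in 1:6) {
    cur <- -x / nu * prev1 + 1 / (2 * nu) * prev2
    expect_equal(inerfc(nu, x), cur, tolerance = 1e-10,
                 label = paste("recurrence order", nu))
    prev2 <- prev1; prev1 <- cur
  }
})

test_that("quadrature route agrees with an independent change of variables", {
  # same integral without the u -> x + s substitution used internally
  nu <- 0.5712; x0 <- 1
  direct <- 2 / (sqrt(pi) * gamma(nu + 1)) *
    integrate(function(u) (u - x0)^nu * exp(-u^2), x0, Inf,
              rel.tol = 1e-12)$value
  expect_equal(inerfc(nu, x0), direct, tolerance = 1e-10)
})

test_that("closed-form field satisfies the boundary and decay conditions", {
  for (n in c(0.2, 0.5712, 1, 2)) {
    p <- diffusion_problem(D = 0.7, k = 2.3, n = n)
    for (t in c(0.25, 1, 4)) {
      expect_equal(diffusion_concentration(p, t, 0), 2.3 * t^(n / 2),
                   tolerance = 1e-9, label = paste("boundary n =", n, "t =", t))
    }
    expect_lt(diffusion_concentration(p, 1, 14 * sqrt(0.7)), 1e-12)
  }
  p0 <- diffusion_problem(1, 1, 0)
  x <- seq(0, 5, by = 0.5)
  expect_equal(diffusion_concentration(p0, 2, x), erfc_ref(x / (2 * sqrt(2))),
               tolerance = 1e-9)
  expect_error(diffusion_concentration(p0, 0, 1), "positive")
})

test_that("released amount matches quadrature of the field and its scaling law", {
  p <- diffusion_problem(D = 1, k = 1, n = 1)
  expect_equal(cumulative_amount(p, 1), gamma(3 / 2) / gamma(2), tolerance = 1e-12)
  for (n in c(0, 0.5712, 1.4)) {
    pn <- diffusion_problem(D = 0.8, k = 1.7, n = n)
    t0 <- 1.3
    expect_equal(cumulative_amount(pn, 4 * t0) / cumulative_amount(pn, t0),
                 4^((n + 1) / 2), tolerance = 1e-12)
    # trapezoid integral of the concentration over a truncated domain
    x <- seq(0, 12 * sqrt(pn$D * t0), length.out = 2001)
    cx <- diffusion_concentration(pn, t0, x)
    trap <- sum(diff(x) * (head(cx, -1) + tail(cx, -1)) / 2)
    expect_equal(trap, cumulative_amount(pn, t0), tolerance = 1e-4,
                 label = paste("quadrature n =", n))
  }
  expect_equal(cumulative_amount(diffusion_problem(1, 1, 0), 1),
               2 * sqrt(1 / pi), tolerance = 1e-12)
})

test_that("finite-difference march reproduces the classical erfc field", {
  p <- diffusion_problem(1, 1, 0)
  sol <- solve_fd(p, t_max = 1, nx = 401, nt = 400)
  j <- length(sol$t)
  idx <- seq(1, length(sol$x), by = 8)
  expect_lt(max(abs(sol$C[idx, j] - erfc_ref(sol$x[idx] / 2))), 5e-5)
})

test_that("grid doubling shows second-order convergence of the solver", {
  p <- diffusion_problem(1, 1, 2)
  err <- sapply(c(1, 2), function(f) {
    sol <- solve_fd(p, t_max = 1, nx = 201 * f, nt = 200 * f)
    idx <- seq(1, length(sol$x), by = 10)
    exact <- diffusion_concentration(p, 1, sol$x[idx])
    max(abs(sol$C[idx, length(sol$t)] - exact))
  })
  expect_gt(err[1] / err[2], 3)
  expect_lt(err[1] / err[2], 5.5)
})

test_that("solver mass balance agrees with the closed-form released amount", {
  p <- diffusion_problem(D = 1, k = 1, n = 0.5)
  sol <- solve_fd(p, t_max = 2, nx = 801, nt = 800)
  j <- length(sol$t)
  cx <- sol$C[, j]
  trap <- sum(diff(sol$x) * (head(cx, -1) + tail(cx, -1)) / 2)
  expect_equal(trap, cumulative_amount(p, 2), tolerance = 1e-4)
})

test_that("truncated domain is checked, not assumed", {
  p <- diffusion_problem(1, 1, 0)
  expect_error(solve_fd(p, t_max = 1, L = 2), "domain too short")
})

test_that("release exponent link inverts the released-amount scaling", {
  expect_equal(release_exponent_link(0.5), 0)
  expect_equal(release_exponent_link(1), 1)
  expect_error(release_exponent_link(0), "positive")
  # a fitted exponent of 0.2856 corresponds to boundary exponent 2n-1;
  # the released amount must then scale as t^0.2856
  n_bc <- release_exponent_link(0.2856)
  expect_equal(n_bc, -0.4288)
  p <- diffusion_problem(D = 1, k = 1, n = n_bc)
  t <- exp(seq(log(1), log(48), length.out = 40))
  slope <- coef(lm(log(cumulative_amount(p, t)) ~ log(t)))[[2]]
  expect_equal(slope, 0.2856, tolerance = 1e-6)
})
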