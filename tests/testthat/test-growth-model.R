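test_that("factor_concentration solves the production/decay balance", {
  # initial condition and steady state
  expect_equal(factor_concentration(0, k1 = 3, k2 = 0.7, n0 = 1.25), 1.25)
  expect_equal(factor_concentration(100 / 0.5, k1 = 2, k2 = 0.5, n0 = 0),
               4.0, tolerance = 1e-10)
  expect_error(factor_concentration(1, k1 = 1, k2 = 0, n0 = 1), "k2")
  expect_error(factor_concentration(-1, k1 = 1, k2 = 1, n0 = 1),
               "non-negative")

  # independent Runge-Kutta oracle for dn/dt = k1 - k2 n
  rk4 <- function(k1, k2, n0, t_end, h = 1e-3) {
    f <- function(n) k1 - k2 * n
    n <- n0
    for (i in seq_len(round(t_end / h))) {
      q1 <- f(n); q2 <- f(n + h / 2 * q1)
      q3 <- f(n + h / 2 * q2); q4 <- f(n + h * q3)
      n <- n + h / 6 * (q1 + 2 * q2 + 2 * q3 + q4)
    }
    n
  }
  expect_equal(factor_concentration(10, k1 = 1, k2 = 0.1, n0 = 0),
               rk4(1, 0.1, 0, 10), tolerance = 1e-8)

  set.seed(41)
  for (i in 1:10) {
    k1 <- runif(1, 0.1, 3); k2 <- runif(1, 0.05, 1); n0 <- runif(1, 0, 5)
    expect_equal(factor_concentration(5, k1, k2, n0), rk4(k1, k2, n0, 5),
                 tolerance = 1e-8)
  }
})

test_that("relative_elongation evaluates the growth law", {
  p <- fit_params(A = 0, B = 0, C = 2.4, D = 1e-4, t_e = 1e4)
  # inflection value C/e
  expect_equal(relative_elongation(p$t_e, p), 2.4 / exp(1),
               tolerance = 1e-14)
  # lower asymptote: sigmoid vanishes far before t_e
  p2 <- fit_params(A = 0, B = 0.5, C = 1, D = 1e-4, t_e = 1e4)
  expect_equal(relative_elongation(p2$t_e - 50 / p2$D, p2), 0.5,
               tolerance = 1e-10)
  # frozen high-precision oracle value at the mean control coefficients
  expect_equal(relative_elongation(36000, mean_control_params()),
               0.12645434433484965, tolerance = 1e-12)
})

test_that("epoch approximations match their closed forms", {
  expect_equal(epoch1_approx(0, 2e-6, 1e5), 0)
  # T1 -> Inf limit leaves the pure linear term
  expect_equal(epoch1_approx(1000, 2e-6, 1e12), 2e-3, tolerance = 1e-9)
  expect_equal(epoch1_approx(1e4, 1e-6, 1e6), 1.005e-2, tolerance = 1e-12)
  expect_error(epoch1_approx(1, 1e-6, -1), "T1")

  p <- fit_params(A = 2e-7, B = 0, C = 1, D = 1e-4, t_e = 1e4)
  expect_equal(epoch2_approx(p$t_e, p), 1 / exp(1), tolerance = 1e-14)
  expect_equal(epoch2_approx(5e4, p), exp(-exp(-4)), tolerance = 1e-14)
  # decomposition: growth law = linear term + late-epoch sigmoid exactly
  tt <- seq(0, 6e4, length.out = 200)
  expect_equal(relative_elongation(tt, p) - p$A * tt, epoch2_approx(tt, p),
               tolerance = 1e-15)
})

test_that("growth_rate is the analytic derivative of the growth law", {
  p <- mean_control_params()
  expect_equal(growth_rate(p$t_e, p), p$C * p$D / exp(1), tolerance = 1e-14)
  expect_equal(growth_rate(p$t_e, p), 3.938885176622633e-06,
               tolerance = 1e-12)
  expect_equal(growth_rate(p$t_e, p, include_linear = TRUE),
               p$C * p$D / exp(1) + p$A, tolerance = 1e-14)

  # finite-difference agreement over random parameter draws
  set.seed(99)
  for (i in 1:200) {
    pp <- fit_params(A = runif(1, 0, 3e-6), B = runif(1, -0.005, 0.01),
                     C = runif(1, 0.03, 0.33), D = runif(1, 9e-5, 5.5e-4),
                     t_e = runif(1, 9800, 24700))
    t0 <- runif(1, 0.5, 1.5) * pp$t_e
    h <- 1e-3 / pp$D
    # fourth-order central stencil keeps the oracle's truncation error well
    # below the comparison tolerance
    y <- function(t) relative_elongation(t, pp)
    fd <- (8 * (y(t0 + h) - y(t0 - h)) - (y(t0 + 2 * h) - y(t0 - 2 * h))) /
      (12 * h)
    expect_equal(growth_rate(t0, pp, include_linear = TRUE), fd,
                 tolerance = 1e-6)
  }
})

test_that("the detrended sigmoid is monotone and bounded by C", {
  set.seed(5)
  for (i in 1:20) {
    p <- fit_params(A = runif(1, 0, 3e-6), B = runif(1, -0.005, 0.01),
                    C = runif(1, 0.03, 0.33), D = runif(1, 9e-5, 5.5e-4),
                    t_e = runif(1, 9800, 24700))
    tt <- seq(0, p$t_e + 8 / p$D, length.out = 500)
    sig <- relative_elongation(tt, p) - p$A * tt - p$B
    expect_true(all(diff(sig) >= -1e-15))
    expect_true(all(sig <= p$C + 1e-12))
    expect_equal(relative_elongation(p$t_e, p) - (p$A * p$t_e + p$B),
                 p$C / exp(1), tolerance = 1e-13)
  }
})

test_that("derive_kinetics maps coefficients to kinetic quantities", {
  p <- mean_control_params()
  kq <- derive_kinetics(p)
  expect_equal(kq$T2, 7751.937984496124, tolerance = 1e-12)
  expect_identical(kq$k2 * kq$T2, 1)
  expect_equal(kq$turgor_proxy, 1.54, tolerance = 1e-12)
  expect_equal(kq$phibar0, p$A)

  # error propagation by total derivatives
  p2 <- fit_params(A = 2e-6, B = 0, C = 0.1, D = 1, t_e = 100,
                   se = c(A = 1e-7, D = 0))
  kq2 <- derive_kinetics(p2)
  expect_identical(kq2$T2, 1)
  expect_identical(kq2$se_T2, 0)
  expect_equal(kq2$se_turgor_proxy, 1e-7 / 1e-6)

  p3 <- fit_params(A = 1e-6, B = 0, C = 0.1, D = 2e-4, t_e = 100,
                   se = c(D = 1e-5))
  expect_equal(derive_kinetics(p3)$se_T2, 1e-5 / (2e-4)^2)

  # invalid parameters are rejected at construction
  expect_error(fit_params(A = 1, B = 0, C = 1, D = -1, t_e = 0), "D")
  expect_error(fit_params(A = 1, B = 0, C = -1, D = 1, t_e = 0), "C")
  expect_error(fit_params(A = 1, B = 0, C = 1, D = 1, t_e = 0,
                          se = c(A = -1)), "standard errors")
})
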