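test_that("impulses sift to a single spike at their separation", {
  n <- 24; d <- 3
  f <- growth_ts(seq_len(n), c(1, rep(0, n - 1)), "pH")
  g <- growth_ts(seq_len(n), c(rep(0, d), 1, rep(0, n - d - 1)), "pH")
  r <- cross_correlate(f, g, max_lag = 6)
  expect_equal(sum(r$ccf != 0), 1)
  expect_equal(r$ccf[r$lags == d], 1)
  expect_equal(r$lag_max, d)
})

test_that("a pure shift is recovered exactly for compact signals", {
  t <- seq(0, 99)
  base <- sin(t / 8) * exp(-((t - 50) / 18)^2)
  f <- growth_ts(t, base, "rate")
  g <- growth_ts(t, c(rep(0, 7), base[1:93]), "rate")
  expect_equal(cross_correlate(f, g)$lag_max, 7)
})

test_that("small hand-computed overlap sums are reproduced", {
  f <- growth_ts(c(0, 1), c(1, 2), "rate")
  r <- cross_correlate(f, f, max_lag = 1)
  expect_equal(r$ccf[r$lags == 0], 5)
  expect_equal(r$ccf[r$lags == 1], 2)
  expect_equal(r$ccf[r$lags == -1], 2)
})

test_that("raw cross-correlation is anti-symmetric under argument swap", {
  set.seed(2)
  for (i in 1:5) {
    t <- seq(0, 63)
    a <- growth_ts(t, rnorm(64), "rate")
    b <- growth_ts(t, rnorm(64), "rate")
    r1 <- cross_correlate(a, b)
    r2 <- cross_correlate(b, a)
    expect_identical(r1$ccf, rev(r2$ccf))
  }
})

test_that("coefficient normalisation is bounded by 1 in magnitude", {
  set.seed(3)
  for (i in 1:5) {
    t <- seq(0, 199)
    a <- growth_ts(t, cumsum(rnorm(200)), "rate")
    b <- growth_ts(t, cumsum(rnorm(200)), "rate")
    r <- cross_correlate(a, b, norm = "coeff")
    expect_true(all(abs(r$ccf) <= 1 + 1e-12))
  }
})

test_that("the lag derivative equals correlating with the time derivative", {
  bp <- bump_pair(dt = 2, span = 2000, shift = 200)
  r <- ccf_derivative(cross_correlate(bp$f, bp$g))
  r2 <- cross_correlate(bp$f, differentiate(bp$g))
  interior <- 2:(length(r$lags) - 1)
  expect_lt(max(abs(r$dccf[interior] - r2$ccf[interior])),
            1e-6 * max(abs(r2$ccf)))
})

test_that("derivative edge cases behave", {
  # linear ccf -> constant derivative, no jump
  bp <- bump_pair()
  r <- cross_correlate(bp$f, bp$g)
  r$ccf <- 2.5 * r$lags + 1
  r <- ccf_derivative(r)
  expect_equal(r$dccf, rep(2.5, length(r$lags)), tolerance = 1e-10)
  r <- jump_at_zero(r, boot = 0)
  expect_equal(r$jump0, 0, tolerance = 1e-10)

  # autocorrelation-like symmetry: dccf is odd about zero lag
  ra <- ccf_derivative(cross_correlate(bp$f, bp$f))
  i0 <- which(ra$lags == 0)
  for (k in 1:5)
    expect_equal(ra$dccf[i0 + k], -ra$dccf[i0 - k], tolerance = 1e-9)
  expect_equal(ra$dccf[i0], 0, tolerance = 1e-9)
})

test_that("the zero-lag jump matches a brute-force two-line fit and is
           bilinear in its inputs", {
  p <- fit_params(0, 0, 0, 1e-4, 9000)  # zero baseline: u is the pure hinge
  mk <- function(break_size) make_ph_pair(
    p, ph0 = 6, dph = 0, onset = 5000, lag = 0, break_size = break_size,
    dt = 10, span = 10000)
  jump_of <- function(pair, window = 5L) {
    r <- ccf_derivative(cross_correlate(pair$ph, pair$elongation))
    jump_at_zero(r, window = window, boot = 50, seed = 2)
  }
  r1 <- jump_of(mk(2e-3))
  # independent oracle: two lm() line fits on the raw ccf about lag 0
  i0 <- which(r1$lags == 0)
  iR <- i0:(i0 + 5); iL <- (i0 - 5):i0
  sR <- unname(coef(lm(r1$ccf[iR] ~ r1$lags[iR]))[2])
  sL <- unname(coef(lm(r1$ccf[iL] ~ r1$lags[iL]))[2])
  expect_equal(r1$jump0, sR - sL, tolerance = 1e-10)
  expect_gt(abs(r1$jump0), 0)

  # linearity in the break size
  r2 <- jump_of(mk(4e-3))
  expect_equal(r2$jump0 / r1$jump0, 2, tolerance = 1e-6)

  # linearity in the pH magnitude
  pair <- mk(2e-3)
  ph2 <- growth_ts(pair$ph$t, 2 * pair$ph$y, "pH")
  r3 <- jump_at_zero(ccf_derivative(
    cross_correlate(ph2, pair$elongation)), boot = 0)
  expect_equal(r3$jump0 / r1$jump0, 2, tolerance = 1e-6)

  # a smooth pair has no genuine discontinuity: its windowed jump estimate
  # is pure curvature leakage and vanishes proportionally to the sampling
  # interval, whereas the kinked pair's jump is refinement-stable
  jump_sm <- function(dt) {
    bp <- bump_pair(dt = dt, span = 2000, shift = 200)
    jump_at_zero(ccf_derivative(
      cross_correlate(bp$f, bp$g, norm = "biased")), boot = 0)$jump0
  }
  expect_equal(jump_sm(1) / jump_sm(2), 0.5, tolerance = 0.05)
  jump_br <- function(dt) {
    pr <- make_ph_pair(fit_params(0, 0, 0, 1e-4, 9000), ph0 = 6, dph = 0,
                       onset = 5000, lag = 0, break_size = 2e-3, dt = dt,
                       span = 10000)
    jump_at_zero(ccf_derivative(
      cross_correlate(pr$ph, pr$elongation, norm = "biased")),
      boot = 0)$jump0
  }
  expect_equal(jump_br(5) / jump_br(10), 1, tolerance = 0.02)

  # window must fit in the lag grid
  expect_error(jump_at_zero(ccf_derivative(
    cross_correlate(pair$ph, pair$elongation, max_lag = 30)),
    window = 10L), "window")
})

test_that("activity profiles preserve ordering and propagate errors", {
  p <- fit_params(0, 0, 0, 1e-4, 9000)
  mk <- function(b) make_ph_pair(p, ph0 = 6, dph = 0, onset = 5000,
                                 lag = 0, break_size = b, dt = 10,
                                 span = 10000)
  ctrl <- mk(1e-3); iaa <- mk(3e-3)
  prof <- activity_profile(list(list(ctrl$ph, ctrl$elongation),
                                list(iaa$ph, iaa$elongation),
                                list(ctrl$ph, ctrl$elongation)),
                           labels = c("control", "IAA", "control2"))
  expect_identical(prof$treatment, c("control", "IAA", "control2"))
  expect_identical(prof$jump0[1], prof$jump0[3])
  expect_equal(prof$jump0[2] / prof$jump0[1], 3, tolerance = 0.01)
  expect_true(all(is.finite(prof$jump0_se)))
  expect_error(activity_profile(list()), "non-empty")
})
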