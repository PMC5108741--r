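test_that("the Lorentzian PSD has the right value, peak and half-power point", {
  expect_equal(lorentzian_psd(2, 0), 0.25)
  expect_equal(lorentzian_psd(2, 2 / (2 * pi)), 1 / (2 * 2^2))
  expect_equal(lorentzian_psd(12.9e-5, 0), 60092542.515473835,
               tolerance = 1e-12)
  expect_error(lorentzian_psd(0, 1), "positive")
  expect_error(lorentzian_psd(-1, 1), "positive")
})

test_that("a bin-centred cosine concentrates its variance in one line", {
  t <- seq(0, 1023)
  a <- 0.7
  fbin <- 32 / 1024
  x <- growth_ts(t, a * cos(2 * pi * fbin * t), "rate")
  sp <- power_spectrum(x, detrend = "none")
  i <- which.max(sp$p)
  expect_equal(sp$f[i], fbin)
  expect_equal(sp$p[i] * sp$df, a^2 / 2, tolerance = 1e-10)
})

test_that("Parseval's identity holds for the one-sided density convention", {
  set.seed(31)
  for (n in c(256, 1001)) {
    x <- growth_ts(seq_len(n) * 2, rnorm(n), "rate")
    sp <- power_spectrum(x, detrend = "mean")
    v <- mean((x$y - mean(x$y))^2)
    expect_equal(sum(sp$p) * sp$df, v, tolerance = 1e-6)
  }
})

test_that("an exponential decay has a Lorentzian spectrum", {
  k <- 1e-3
  r <- make_multifactor_rate(data.frame(x = 1, w = 1, k = k),
                             PY = 1, phi0 = 1, dt = 1, span = 20000)
  sp <- power_spectrum(r, detrend = "none")
  sel <- sp$f > 0 & sp$f < 10 * k / (2 * pi)
  ratio <- sp$p[sel] / lorentzian_psd(k, sp$f[sel])
  expect_lt(max(abs(ratio / ratio[1] - 1)), 0.02)
})

test_that("zero-frequency intensity scales as 1/k^2", {
  p0 <- function(k) {
    r <- make_multifactor_rate(data.frame(x = 1, w = 1, k = k),
                               PY = 1, phi0 = 1, dt = 1, span = 200000)
    zero_frequency_intensity(power_spectrum(r, detrend = "none"))
  }
  # doubling k quarters the intensity
  expect_equal(p0(5e-4) / p0(1e-3), 4, tolerance = 0.03)
  # log-log slope -2 across a decade
  ks <- 10^seq(-3.5, -2.5, length.out = 6)
  slope <- unname(coef(lm(log(vapply(ks, p0, 0)) ~ log(ks)))[2])
  expect_equal(slope, -2, tolerance = 0.05 / 2)

  # degenerate readings
  z <- growth_ts(seq_len(64), rep(0, 64), "rate")
  expect_equal(zero_frequency_intensity(power_spectrum(z, "none")), 0)
  # mean removal zeroes the f = 0 bin, hence intensity readings use the
  # undetrended spectrum
  r <- make_multifactor_rate(data.frame(x = 1, w = 1, k = 1e-3),
                             PY = 1, phi0 = 1, dt = 1, span = 20000)
  sp_d <- power_spectrum(r, detrend = "mean")
  sp_n <- power_spectrum(r, detrend = "none")
  expect_lt(zero_frequency_intensity(sp_d),
            1e-12 * zero_frequency_intensity(sp_n))
})

test_that("non-uniform sampling is refused", {
  set.seed(8)
  t <- cumsum(runif(64, 0.5, 1.5))
  expect_error(power_spectrum(growth_ts(t, rnorm(64), "rate")),
               "resample-required")
})

test_that("fit_lorentzian recovers decay rates from spectra", {
  r <- make_multifactor_rate(data.frame(x = 1, w = 1, k = 5e-4),
                             PY = 1, phi0 = 1, dt = 1, span = 60000)
  fl <- fit_lorentzian(power_spectrum(r, detrend = "none"))
  expect_lt(rel_err(fl$k, 5e-4), 0.05)
  expect_false(fl$at_boundary)

  # two well-separated components: the slow one dominates the low band
  r2 <- make_multifactor_rate(
    data.frame(x = c(0.5, 0.5), w = c(0.5, 0.5), k = c(1e-4, 2e-3)),
    PY = 1, phi0 = 1, dt = 1, span = 100000)
  fl2 <- fit_lorentzian(power_spectrum(r2, detrend = "none"),
                        f_cutoff = 1e-4)
  expect_lt(rel_err(fl2$k, 1e-4), 0.10)

  # a 1/f^2-type spectrum drives k to its lower bound and is flagged
  set.seed(12)
  bm <- growth_ts(seq_len(2048), cumsum(rnorm(2048)), "rate")
  flb <- fit_lorentzian(power_spectrum(bm, detrend = "mean"))
  expect_true(flb$at_boundary)
})

test_that("well-separated components superpose in the spectrum", {
  mk <- function(x1, x2) make_multifactor_rate(
    data.frame(x = c(x1, x2), w = c(0.5, 0.5), k = c(1e-4, 1e-2)),
    PY = 1, phi0 = 1, dt = 1, span = 100000)
  sp_sum <- power_spectrum(mk(0.5, 0.5), detrend = "none")
  sp_1 <- power_spectrum(mk(0.5, 0), detrend = "none")
  sp_2 <- power_spectrum(mk(0, 0.5), detrend = "none")
  sel <- sp_sum$f < 1e-4 / (2 * pi)  # within the slow component's width
  expect_lt(max(abs(sp_sum$p[sel] - (sp_1$p[sel] + sp_2$p[sel])) /
                  sp_sum$p[sel]), 0.03)
})
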