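#' Lorentzian power spectral density of an exponentially relaxing process
#'
#' A growth-rate component decaying as `exp(-k t)` contributes a Lorentzian
#' \deqn{P(f) = \frac{1}{k^2 + 4 \pi^2 f^2}}
#' to the growth-rate power spectrum (up to the component's intensity). The
#' maximum sits at `f = 0` with value `1/k^2`, so the zero-frequency
#' intensity ranks treatments by the reciprocal square of their diffusion
#' rate.
#'
#' @param k Decay (diffusion) rate constant (s^-1), positive.
#' @param f Frequency (Hz); vectorised.
#' @return Relative power (arbitrary units of 1/k^2).
#' @examples
#' lorentzian_psd(2, 0)          # 0.25
#' lorentzian_psd(2, 2 / (2 * pi))  # half power
#' @export
lorentzian_psd <- function(k, f) {
  if (!is.finite(k) || k <= 0) stop("`k` must be positive", call. = FALSE)
  1 / (k^2 + 4 * pi^2 * f^2)
}

#' One-sided power spectral density of a growth-rate record
#'
#' Discrete Fourier transform of the (optionally detrended) series with
#' one-sided density normalisation: `p[j] = |X[j]|^2 * dt / n` doubled at
#' the interior frequencies, on the grid `f = 0, df, ..., f_Nyquist` with
#' `df = 1/(n*dt)`. Under this convention Parseval's identity reads
#' `sum(p) * df = mean(x^2)` of the analysed (detrended) series.
#'
#' Zero-frequency intensity readings (the non-oscillatory process
#' intensity, proportional to `1/k^2` for an exponentially relaxing
#' component) must be taken with `detrend = "none"`: mean removal zeroes
#' the `f = 0` bin by construction. Detrending is for examining the
#' oscillatory remainder.
#'
#' @param rate A `growth_ts` (normally kind `rate`), uniformly sampled
#'   (at most 1% sampling jitter) with at least 16 points.
#' @param detrend One of `"none"`, `"mean"`, `"linear"`, or `"model"`.
#'   `"model"` subtracts the analytic rate trend of a growth-law fit
#'   supplied via `model_params`.
#' @param model_params A [fit_params()] used when `detrend = "model"`.
#' @return A list of class `power_spectrum`: `f` (Hz), `p` (rate^2 s),
#'   `df`, `detrend`.
#' @export
power_spectrum <- function(rate,
                           detrend = c("none", "mean", "linear", "model"),
                           model_params = NULL) {
  detrend <- match.arg(detrend)
  if (!inherits(rate, "growth_ts"))
    stop("expected a growth_ts object", call. = FALSE)
  n <- length(rate$t)
  if (n < 16L) stop("need at least 16 samples", call. = FALSE)
  if (!ts_is_uniform(rate, tol = 0.01))
    stop("resample-required: sampling jitter exceeds 1%; use resample_uniform()",
         call. = FALSE)
  dt <- ts_dt(rate)
  x <- rate$y

  trend <- switch(detrend,
                  none = rep(0, n),
                  mean = rep(mean(x), n),
                  linear = stats::fitted(stats::lm(x ~ rate$t)),
                  model = {
                    if (is.null(model_params))
                      stop("`model_params` required for detrend = \"model\"",
                           call. = FALSE)
                    growth_rate(rate$t, model_params, include_linear = TRUE)
                  })
  xd <- x - trend

  n_half <- floor(n / 2)
  df <- 1 / (n * dt)
  f <- (0:n_half) * df

  psd_of <- function(z) {
    X <- stats::fft(z)[1:(n_half + 1)]
    p <- (Mod(X)^2) * dt / n
    # fold negative frequencies: double everything except DC and (n even) the
    # Nyquist bin, which have no mirror image
    last_double <- if (n %% 2 == 0) n_half else n_half + 1
    if (last_double >= 2) p[2:last_double] <- 2 * p[2:last_double]
    p
  }
  p <- psd_of(xd)
  structure(list(f = f, p = p, df = df, detrend = detrend, n = n, dt = dt),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, df = %.3g Hz, Nyquist = %.3g Hz, detrend = %s\n",
              length(x$f), x$df, x$f[length(x$f)], x$detrend))
  invisible(x)
}

#' Zero-frequency intensity of a power spectrum
#'
#' The reading at `f = 0`, proportional to `1/k^2` for an exponentially
#' decaying growth-rate component: the intensity of the non-oscillatory
#' growth process. Compute the spectrum with `detrend = "none"` for this
#' reading; any mean-removing detrend leaves the bin identically ~0.
#'
#' @param spec A `power_spectrum`.
#' @return Intensity (rate^2 s).
#' @export
zero_frequency_intensity <- function(spec) {
  stopifnot(inherits(spec, "power_spectrum"))
  spec$p[1]
}

#' Fit a Lorentzian to the low-frequency part of a spectrum
#'
#' Least-squares fit of `c / (k^2 + 4 pi^2 f^2)` over frequencies below
#' `f_cutoff`, inverting the Lorentzian shape to recover the dominant decay
#' rate of the underlying growth-rate relaxation.
#'
#' @param spec A `power_spectrum`.
#' @param f_cutoff Upper frequency bound of the fit window (Hz); defaults
#'   to one fifth of the Nyquist frequency.
#' @return A list with `k` (s^-1), `c`, their standard errors `se_k`,
#'   `se_c`, and `at_boundary` (`TRUE` when the fitted `k` collapsed to the
#'   lower bound, e.g. for a flat spectrum).
#' @export
fit_lorentzian <- function(spec, f_cutoff = NULL) {
  stopifnot(inherits(spec, "power_spectrum"))
  if (is.null(f_cutoff)) f_cutoff <- spec$f[length(spec$f)] / 5
  # skip the f = 0 bin: it is not doubled by the one-sided folding and for
  # detrended spectra it is structurally ~0, either way off the Lorentzian
  sel <- spec$f > 0 & spec$f <= f_cutoff
  f <- spec$f[sel]
  p <- spec$p[sel]
  if (sum(sel) < 4L) stop("fit window holds fewer than 4 bins", call. = FALSE)

  p0 <- max(p[1], max(p) * 1e-12)
  # half-power frequency -> k0 = 2 pi f_half
  i_half <- which(p <= p0 / 2)[1]
  k0 <- if (is.finite(i_half) && !is.na(i_half)) 2 * pi * f[i_half]
        else 2 * pi * f_cutoff / 2
  k_lo <- 1e-12
  if (k0 <= k_lo) k0 <- 2 * pi * spec$df
  c0 <- p0 * k0^2

  resid_fn <- function(par) p - par[["c"]] / (par[["k"]]^2 + 4 * pi^2 * f^2)
  res <- tryCatch(
    minpack.lm::nls.lm(par = c(k = k0, c = c0),
                       lower = c(k = k_lo, c = 0),
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(res) || !res$info %in% 1:4)
    stop("Lorentzian fit did not converge", call. = FALSE)
  par <- res$par
  s2 <- res$deviance / max(length(p) - 2L, 1L)
  se <- tryCatch(sqrt(diag(s2 * solve(res$hessian))),
                 error = function(e) c(NA_real_, NA_real_))
  list(k = par[["k"]], c = par[["c"]],
       se_k = se[[1]], se_c = se[[2]],
       at_boundary = par[["k"]] <= k_lo * 10)
}
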