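#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a relative-elongation growth curve
#'
#' Forward growth law plus iid Gaussian noise, the synthetic counterpart of
#' a digitized coleoptile elongation record. The default noise level is
#' 0.5% of the growth amplitude `C`, matching the visual scatter of
#' published curves. Bit-reproducible for a fixed seed.
#'
#' @param truth A [fit_params()] of true coefficients.
#' @param dt Sampling interval (s).
#' @param span Record length (s); the record covers `[0, span]`.
#' @param noise_sd Gaussian noise SD in relative-elongation units;
#'   `NULL` picks `0.005 * C`.
#' @param seed Integer seed.
#' @return A `growth_ts` of kind `relative_elongation`.
#' @examples
#' p <- fit_params(A = 15.4e-7, B = 9e-4, C = 0.083, D = 12.9e-5, t_e = 22205)
#' s <- make_growth_curve(p, dt = 60, span = 36000, seed = 42)
#' @export
make_growth_curve <- function(truth, dt = 60, span = 36000,
                              noise_sd = NULL, seed = 1L) {
  truth <- as_fit_params(truth)
  if (dt <= 0 || span < 10 * dt)
    stop("`span` must cover at least 10 sampling intervals", call. = FALSE)
  if (is.null(noise_sd)) noise_sd <- 0.005 * truth$C
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  t <- seq(0, span, by = dt)
  y <- relative_elongation(t, truth)
  if (noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  growth_ts(t, y, kind = "relative_elongation", label = "synthetic")
}

#' Simulate a multi-factor growth-rate record
#'
#' Growth rate as the weighted sum of exponentially decaying wall-loosening
#' factor components under the Lockhart/Ortega viscoplastic term (elastic
#' term neglected, constant turgor excess):
#' \deqn{GR(t) = \Phi_0 (P - Y) \sum_i (x_i / w_i) e^{-k_i t} + noise,}
#' with positive weights constrained to sum to 1. Each component imprints a
#' Lorentzian of width `k_i` on the rate power spectrum.
#'
#' @param components Data frame with columns `x` (constituent
#'   concentration), `w` (positive weight, summing to 1 within 1e-9) and
#'   `k` (decay rate, s^-1, non-negative).
#' @param PY Constant turgor excess `P - Y` (MPa), positive.
#' @param phi0 Lockhart extensibility constant (MPa^-1 s^-1).
#' @param dt,span,noise_sd,seed As in [make_growth_curve()]; `noise_sd`
#'   defaults to 0 (rate units).
#' @return A `growth_ts` of kind `rate`.
#' @export
make_multifactor_rate <- function(components, PY = 0.3, phi0 = 1e-6,
                                  dt = 1, span = 20000, noise_sd = 0,
                                  seed = 1L) {
  stopifnot(is.data.frame(components),
            all(c("x", "w", "k") %in% names(components)))
  if (any(components$w <= 0))
    stop("weights must be positive", call. = FALSE)
  if (abs(sum(components$w) - 1) > 1e-9)
    stop("weights must sum to 1 (completeness relation)", call. = FALSE)
  if (any(components$k < 0))
    stop("decay rates must be non-negative", call. = FALSE)
  if (PY <= 0) stop("`PY` (turgor excess) must be positive", call. = FALSE)
  if (dt <= 0 || span < 10 * dt)
    stop("`span` must cover at least 10 sampling intervals", call. = FALSE)
  t <- seq(0, span, by = dt)
  gr <- rep(0, length(t))
  for (i in seq_len(nrow(components)))
    gr <- gr + (components$x[i] / components$w[i]) * exp(-components$k[i] * t)
  gr <- phi0 * PY * gr
  if (noise_sd > 0)
    gr <- gr + with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  growth_ts(t, gr, kind = "rate", label = "synthetic")
}

#' Simulate a paired pH / elongation record
#'
#' Emulates the joint structure of medium-pH and elongation traces. Two
#' acidification profiles are available:
#' \describe{
#'   \item{`"exponential"`}{stimulus-onset acidification
#'     \eqn{pH(t) = pH_0 - \Delta pH (1 - e^{-r (t - onset)})} for
#'     `t >= onset` (flat before).}
#'   \item{`"mirror"`}{acid-growth coupling: the acidification tracks the
#'     growth sigmoid itself, `pH(t) = pH0 - dph * s(t)` with `s` the
#'     normalised sigmoid of `truth` (inflection at `t_e`). Because the
#'     elongation is the same waveform delayed by `lag`, the two rate
#'     pulses are exact shifted copies and a cross-correlation of the
#'     rates recovers `lag` at sample resolution.}
#' }
#' The elongation record follows the growth law delayed by `lag` relative
#' to the pH response, with an optional slope break of size `break_size`
#' (um/s) added at `onset + lag` so the zero-lag derivative-jump estimator
#' has a known discontinuity to detect.
#'
#' @param truth A [fit_params()] describing the elongation curve (evaluated
#'   in relative-elongation units and scaled by `L0` to micrometres).
#' @param ph0 Baseline pH.
#' @param dph Acidification depth (pH units); 0 gives a flat trace.
#' @param onset Stimulus onset (s), inside `[0, span]`.
#' @param ph_rate Acidification rate constant (s^-1).
#' @param lag Delay of the elongation response relative to pH (s).
#' @param ph_profile `"exponential"` or `"mirror"` (see Description).
#' @param break_size Slope discontinuity added to the elongation (um/s) at
#'   `onset + lag`.
#' @param L0 Scale from relative elongation to micrometres.
#' @param dt,span Sampling interval and record length (s).
#' @param noise_sd_ph,noise_sd_u Gaussian noise SDs for the two records.
#' @param seed Integer seed.
#' @return A list with elements `ph` and `elongation` (`growth_ts` of kinds
#'   `pH` and `elongation`) plus the generating parameters as attributes.
#' @export
make_ph_pair <- function(truth, ph0 = 6.2, dph = 0.5, onset = 3600,
                         ph_rate = 1 / 900, lag = 420, break_size = 0,
                         L0 = 10000, dt = 10, span = 18000,
                         noise_sd_ph = 0, noise_sd_u = 0, seed = 1L,
                         ph_profile = c("exponential", "mirror")) {
  ph_profile <- match.arg(ph_profile)
  truth <- as_fit_params(truth)
  if (onset < 0 || onset > span)
    stop("`onset` must lie inside the record span", call. = FALSE)
  if (dt <= 0 || span < 10 * dt)
    stop("`span` must cover at least 10 sampling intervals", call. = FALSE)
  t <- seq(0, span, by = dt)

  if (ph_profile == "exponential") {
    ph <- rep(ph0, length(t))
    after <- t >= onset
    ph[after] <- ph0 - dph * (1 - exp(-ph_rate * (t[after] - onset)))
  } else {
    s <- exp(-exp(-truth$D * (t - truth$t_e)))  # normalised growth sigmoid
    ph <- ph0 - dph * s
  }

  u <- L0 * relative_elongation(t - lag, truth)
  tb <- onset + lag
  u <- u + break_size * pmax(t - tb, 0)

  if (noise_sd_ph > 0 || noise_sd_u > 0) {
    noise <- with_seed(seed, list(
      ph = stats::rnorm(length(t), 0, max(noise_sd_ph, 0)),
      u = stats::rnorm(length(t), 0, max(noise_sd_u, 0))))
    ph <- ph + noise$ph
    u <- u + noise$u
  }
  out <- list(ph = growth_ts(t, ph, kind = "pH", label = "synthetic"),
              elongation = growth_ts(t, u, kind = "elongation",
                                     label = "synthetic"))
  attr(out, "lag") <- lag
  attr(out, "onset") <- onset
  attr(out, "break_size") <- break_size
  out
}
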