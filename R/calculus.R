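#' Cumulative elongation from a growth-rate record
#'
#' Numerically integrates a rate series (trapezoidal rule) to recover the
#' elongation record, \eqn{u(t) = u_0 + \int_{t_0}^{t} v \, dt'}. This is how
#' elongation curves are reconstructed when only growth-rate traces are
#' published.
#'
#' @param rate A `growth_ts` of kind `rate`, uniformly or near-uniformly
#'   sampled.
#' @param u0 Elongation at the first sample (same units as the integral of
#'   the rate; 0 by default).
#' @return A `growth_ts` of kind `elongation` with first value `u0`.
#' @export
cumulative_elongation <- function(rate, u0 = 0) {
  stopifnot_kind(rate, "rate")
  if (length(rate$t) < 2L)
    stop("need at least 2 samples to integrate", call. = FALSE)
  u <- u0 + pracma::cumtrapz(rate$t, rate$y)[, 1]
  growth_ts(rate$t, u, kind = "elongation", label = rate$label)
}

#' Growth rate from an elongation record
#'
#' Finite-difference time derivative: central differences at interior
#' samples, second-order one-sided stencils at the two ends. Exact for
#' quadratics on uniform grids.
#'
#' @param elong A `growth_ts` of kind `elongation` or `relative_elongation`
#'   with at least 3 points.
#' @return A `growth_ts` of kind `rate` on the same time grid.
#' @export
differentiate <- function(elong) {
  stopifnot_kind(elong, c("elongation", "relative_elongation"))
  t <- elong$t
  y <- elong$y
  n <- length(t)
  if (n < 3L) stop("need at least 3 points to differentiate", call. = FALSE)
  v <- numeric(n)
  # second-order one-sided stencils at the ends (uniform-grid form)
  v[1] <- (-3 * y[1] + 4 * y[2] - y[3]) / (t[3] - t[1])
  v[n] <- (3 * y[n] - 4 * y[n - 1] + y[n - 2]) / (t[n] - t[n - 2])
  idx <- 2:(n - 1)
  v[idx] <- (y[idx + 1] - y[idx - 1]) / (t[idx + 1] - t[idx - 1])
  growth_ts(t, v, kind = "rate", label = elong$label)
}

#' Peak statistics of a growth-rate record
#'
#' Locates the main peak of a rate trace (global maximum after centred
#' moving-average smoothing), measures its height and full width at half
#' maximum (half-maximum crossings by linear interpolation), and summarises
#' the record by its total growth (trapezoidal integral of the rate) and
#' total growth rate. Peak times are seconds internally; divide by 60 for
#' the minute convention of published summary tables.
#'
#' @param rate A `growth_ts` of kind `rate`.
#' @param smooth_window Odd width (samples) of the centred moving average
#'   applied before peak detection; 5 by default.
#' @param rate_summary How the "total growth rate" is summarised:
#'   `"mean"` is the arithmetic mean of the rate samples, `"integral"` is
#'   total growth divided by the record duration. Both are reported; this
#'   flag picks which fills `total_growth_rate`.
#' @return A list of class `peak_stats`: `peak_time` (s), `peak_height`,
#'   `half_width` (s, `NA` with `has_peak = FALSE` when the maximum sits on
#'   the record boundary), `total_growth`, `total_growth_rate`,
#'   `total_growth_rate_mean`, `total_growth_rate_integral`, `has_peak`.
#' @export
peak_stats <- function(rate, smooth_window = 5L,
                       rate_summary = c("mean", "integral")) {
  stopifnot_kind(rate, "rate")
  rate_summary <- match.arg(rate_summary)
  t <- rate$t
  y <- rate$y
  n <- length(y)
  k <- min(as.integer(smooth_window), n)
  if (k %% 2L == 0L) k <- k - 1L
  if (k < 1L) k <- 1L
  ys <- if (k > 1L) {
    sm <- stats::filter(y, rep(1 / k, k), sides = 2)
    sm <- as.numeric(sm)
    # keep raw values where the window does not fit (record edges)
    sm[is.na(sm)] <- y[is.na(sm)]
    sm
  } else y

  i_pk <- which.max(ys)
  peak_time <- t[i_pk]
  peak_height <- ys[i_pk]
  has_peak <- i_pk > 1L && i_pk < n

  half_width <- NA_real_
  if (has_peak) {
    half <- peak_height / 2
    # last crossing before the peak
    left <- NA_real_
    for (i in seq(i_pk, 2L)) {
      if (ys[i - 1] <= half && ys[i] >= half) {
        left <- t[i - 1] + (half - ys[i - 1]) * (t[i] - t[i - 1]) /
          (ys[i] - ys[i - 1])
        break
      }
    }
    right <- NA_real_
    for (i in seq(i_pk, n - 1L)) {
      if (ys[i] >= half && ys[i + 1] <= half) {
        right <- t[i] + (ys[i] - half) * (t[i + 1] - t[i]) /
          (ys[i] - ys[i + 1])
        break
      }
    }
    if (is.finite(left) && is.finite(right)) half_width <- right - left
  }

  total_growth <- pracma::trapz(t, y)
  duration <- t[n] - t[1]
  out <- list(peak_time = peak_time,
              peak_height = peak_height,
              half_width = half_width,
              total_growth = total_growth,
              total_growth_rate_mean = mean(y),
              total_growth_rate_integral = total_growth / duration,
              has_peak = has_peak)
  out$total_growth_rate <- switch(rate_summary,
                                  mean = out$total_growth_rate_mean,
                                  integral = out$total_growth_rate_integral)
  class(out) <- "peak_stats"
  out
}

#' @export
print.peak_stats <- function(x, ...) {
  cat(sprintf("<peak_stats> peak at %.4g s (%.4g min), height %.4g, FWHM %.4g s, total growth %.4g\n",
              x$peak_time, x$peak_time / 60, x$peak_height, x$half_width,
              x$total_growth))
  invisible(x)
}

#' Summarise peak statistics over replicate rate records
#'
#' Mean and sample SD of total growth, peak location (minutes) and total
#' growth rate across replicates, the shape of published per-treatment
#' summary tables.
#'
#' @param rates A list of `growth_ts` rate records (one treatment).
#' @param label Treatment label for the output row.
#' @param ... Passed to [peak_stats()].
#' @return One-row data frame: `treatment`, `n`, `total_growth`,
#'   `total_growth_sd`, `peak_at_min`, `peak_at_min_sd`,
#'   `total_growth_rate`, `total_growth_rate_sd`.
#' @export
peak_stats_table <- function(rates, label = "", ...) {
  if (length(rates) < 1L) stop("need at least one record", call. = FALSE)
  ss <- lapply(rates, peak_stats, ...)
  tg <- vapply(ss, `[[`, 0, "total_growth")
  pk <- vapply(ss, `[[`, 0, "peak_time") / 60
  gr <- vapply(ss, `[[`, 0, "total_growth_rate")
  sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  data.frame(treatment = label, n = length(ss),
             total_growth = mean(tg), total_growth_sd = sd0(tg),
             peak_at_min = mean(pk), peak_at_min_sd = sd0(pk),
             total_growth_rate = mean(gr), total_growth_rate_sd = sd0(gr))
}
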