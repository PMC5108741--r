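#' Data-driven starting values for the growth-law fit
#'
#' Builds a heuristic initial [fit_params()] from a relative-elongation
#' record: `A0`/`B0` from a least-squares line through the first 20% of
#' samples (the linear start-up region), `t_e0` at the earliest maximum of
#' the smoothed finite-difference rate (growth onset), `D0` from the 10%-90%
#' rise duration of the detrended amplitude scaled by
#' `log(log(10)/log(10/9))` (the exact 10-90 rise factor of the Gompertz
#' sigmoid), and `C0` as the detrended amplitude at the last sample.
#'
#' @param series A `growth_ts` of kind `relative_elongation` with at least
#'   10 points spanning the sigmoidal rise.
#' @param noise_floor Amplitude scale below which the series is declared
#'   signal-free; defaults to 10x the median absolute first difference.
#' @return A [fit_params()] of starting values.
#' @export
initialize_growth_fit <- function(series, noise_floor = NULL) {
  stopifnot_kind(series, "relative_elongation")
  t <- series$t
  y <- series$y
  n <- length(t)
  if (n < 10L)
    stop("need at least 10 points spanning the sigmoidal rise", call. = FALSE)

  # smoothed finite-difference rate; earliest maximum = growth onset.
  # The window grows with the sample count so dense noisy records still
  # yield a stable onset estimate.
  rate <- diff(y) / diff(t)
  k <- min(max(5L, round(n / 40)), length(rate))
  if (k %% 2 == 0) k <- k - 1L
  sm <- stats::filter(rate, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- -Inf
  i_max <- which.max(sm)  # which.max returns the first (earliest) maximum
  te0 <- (t[i_max] + t[i_max + 1]) / 2

  # start-up line fitted before the rise: samples up to half the onset time
  # (a fixed head fraction would swallow the sigmoid when t_e sits early)
  head_idx <- which(t <= t[1] + 0.5 * (te0 - t[1]))
  if (length(head_idx) < max(5L, floor(0.05 * n)))
    head_idx <- seq_len(max(5L, floor(0.05 * n)))
  lf <- stats::lm.fit(cbind(1, t[head_idx]), y[head_idx])
  B0 <- unname(lf$coefficients[1])
  A0 <- max(unname(lf$coefficients[2]), 0)

  detr <- y - (A0 * t + B0)
  detr <- detr - min(detr)
  amp <- detr[n]
  if (is.null(noise_floor))
    noise_floor <- stats::median(abs(diff(y)))
  if (!is.finite(amp) || amp <= 10 * noise_floor)
    stop("no-signal: series has no sigmoidal amplitude above the noise floor",
         call. = FALSE)

  t10 <- t[which(detr >= 0.1 * amp)[1]]
  t90 <- t[which(detr >= 0.9 * amp)[1]]
  rise <- t90 - t10
  if (!is.finite(rise) || rise <= 0) rise <- (t[n] - t[1]) / 4
  D0 <- log(log(10) / log(10 / 9)) / rise

  fit_params(A = A0, B = B0, C = max(amp, .Machine$double.eps),
             D = D0, t_e = te0)
}

#' Fit the growth law to a relative-elongation series
#'
#' Bounded Levenberg-Marquardt least squares of
#' `y = A*t + B + C*exp(-exp(-D*(t - t_e)))` with default bounds
#' `A >= 0`, `C >= 0`, `D > 0` and `t_e` within the record span extended by
#' one span on either side. On failure the initial values are jittered and
#' the fit restarted (up to `restarts` times, seeded for reproducibility).
#' Standard errors come from the inverse curvature (Jacobian cross-product)
#' at the optimum scaled by the residual variance. A solution with `D` on
#' its bound is refused: it means the sigmoid time scale was not identified.
#'
#' @param series A `growth_ts` of kind `relative_elongation` (an
#'   `elongation` record can be converted first with
#'   [to_relative_elongation()]).
#' @param init Optional [fit_params()] starting values; computed by
#'   [initialize_growth_fit()] when omitted.
#' @param lower,upper Optional named bound vectors (`A`, `B`, `C`, `D`,
#'   `t_e`) overriding the defaults.
#' @param restarts Number of jittered restarts after a failed attempt.
#' @param seed Integer seed for the restart jitter.
#' @return A list of class `growth_fit`: `params` ([fit_params()] with
#'   standard errors and `rss`), `converged`, `n_points`, `residual_sd`,
#'   `init_used`, and `fitted`/`residuals` vectors.
#' @examples
#' p <- fit_params(A = 15.4e-7, B = 9e-4, C = 0.083, D = 12.9e-5, t_e = 22205)
#' tt <- seq(0, 36000, length.out = 200)
#' ts <- growth_ts(tt, relative_elongation(tt, p), "relative_elongation")
#' fit_growth(ts)$params
#' @export
fit_growth <- function(series, init = NULL, lower = NULL, upper = NULL,
                       restarts = 5L, seed = 1L) {
  stopifnot_kind(series, c("relative_elongation"))
  t <- series$t
  y <- series$y
  span <- t[length(t)] - t[1]

  if (is.null(init)) init <- initialize_growth_fit(series)
  init <- as_fit_params(init)

  lo <- c(A = 0, B = -Inf, C = 0, D = 1e-12,
          t_e = t[1] - span)
  up <- c(A = Inf, B = Inf, C = Inf, D = Inf,
          t_e = t[length(t)] + span)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) up[names(upper)] <- upper

  start0 <- c(A = init$A, B = init$B, C = init$C, D = init$D, t_e = init$t_e)
  start0 <- pmin(pmax(start0, lo), up)

  model <- function(par, tt) {
    par[["A"]] * tt + par[["B"]] +
      par[["C"]] * exp(-exp(-par[["D"]] * (tt - par[["t_e"]])))
  }
  resid_fn <- function(par) y - model(par, t)

  rng <- local({
    r <- NULL
    withr_seed <- seed
    function() {
      # lightweight private RNG stream for jitter, leaves .Random.seed alone
      withr_seed <<- (1103515245 * withr_seed + 12345) %% 2^31
      withr_seed / 2^31
    }
  })

  best <- NULL
  for (attempt in seq_len(restarts + 1L)) {
    start <- start0
    if (attempt > 1L) {
      jit <- vapply(seq_along(start), function(i) 2 * rng() - 1, 0)
      start <- start * (1 + 0.3 * jit)
      start[["t_e"]] <- start0[["t_e"]] + 0.15 * span * jit[5]
      start <- pmin(pmax(start, lo), up)
    }
    res <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lo, upper = up, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(res)) next
    ok <- res$info %in% 1:4
    # a solution with the amplitude C collapsed onto its bound is a
    # degenerate basin, not a usable fit; keep jittering
    degenerate <- res$par[["C"]] <= lo[["C"]] + .Machine$double.eps
    if (ok && !degenerate &&
        (is.null(best) || res$deviance < best$deviance)) best <- res
    if (!is.null(best) && attempt == 1L) break
  }

  if (is.null(best))
    stop("fit-failure: Levenberg-Marquardt did not converge after restarts",
         call. = FALSE)

  par <- best$par
  d_rel <- (par[["D"]] - lo[["D"]]) / max(par[["D"]], lo[["D"]])
  if (par[["D"]] <= lo[["D"]] * (1 + 1e-8) ||
      (is.finite(up[["D"]]) && par[["D"]] >= up[["D"]] * (1 - 1e-8)))
    stop("boundary-solution: `D` hit its bound; sigmoid time scale not identified",
         call. = FALSE)

  n <- length(y)
  rss <- best$deviance
  dof <- n - 5L
  s2 <- rss / max(dof, 1L)
  se <- rep(NA_real_, 5)
  names(se) <- names(par)
  # the coefficient scales differ by ~10 orders of magnitude, so the raw
  # curvature matrix is numerically singular; equilibrate it before
  # inverting rather than refusing standard errors
  se <- tryCatch({
    h <- best$hessian
    d <- sqrt(diag(h))
    hs <- h / (d %o% d)
    cv <- (s2 * solve(hs, tol = 0)) / (d %o% d)
    dg <- diag(cv)
    dg[dg < 0] <- NA_real_
    stats::setNames(sqrt(dg), names(par))
  }, error = function(e) se)

  params <- fit_params(par[["A"]], par[["B"]], par[["C"]], par[["D"]],
                       par[["t_e"]],
                       se = c(A = se[["A"]], B = se[["B"]], C = se[["C"]],
                              D = se[["D"]], t_e = se[["t_e"]]),
                       rss = rss)
  structure(list(params = params,
                 converged = TRUE,
                 n_points = n,
                 residual_sd = sqrt(s2),
                 init_used = init,
                 fitted = model(par, t),
                 residuals = resid_fn(par)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> converged=%s n=%d residual sd=%.3g\n",
              x$converged, x$n_points, x$residual_sd))
  print(x$params)
  invisible(x)
}

#' Aggregate replicate growth fits into mean coefficients
#'
#' Arithmetic mean and sample SD per coefficient over converged replicate
#' fits, with the total-derivative (propagated) error of the mean reported
#' separately: `se_td = sqrt(sum(se_i^2)) / n`, the first-order propagation
#' of the per-fit standard errors through the averaging.
#'
#' @param fits A list of `growth_fit` objects (at least 2).
#' @return A data frame with one row per coefficient (`A`, `B`, `C`, `D`,
#'   `t_e`) and columns `mean`, `sd`, `se_td`, `n`.
#' @examples
#' # Table-style aggregation of two control fits
#' f1 <- fit_params(14.0e-7, 0.0017, 0.087, 12.6e-5, 22330)
#' f2 <- fit_params(16.7e-7, 0.0002, 0.079, 13.2e-5, 22080)
#' aggregate_fits(list(f1, f2))
#' @export
aggregate_fits <- function(fits) {
  if (length(fits) < 2L)
    stop("insufficient-replicates: need at least 2 converged fits",
         call. = FALSE)
  ps <- lapply(fits, function(f) {
    if (inherits(f, "growth_fit")) {
      if (!isTRUE(f$converged))
        stop("all fits must be converged", call. = FALSE)
      f$params
    } else as_fit_params(f)
  })
  coefs <- c("A", "B", "C", "D", "t_e")
  mat <- vapply(ps, function(p) unlist(p[coefs]), numeric(5))
  ses <- vapply(ps, function(p) p$se[coefs], numeric(5))
  n <- length(ps)
  data.frame(
    coefficient = coefs,
    mean = rowMeans(mat),
    sd = apply(mat, 1, stats::sd),
    se_td = sqrt(rowSums(ses^2, na.rm = FALSE)) / n,
    n = n,
    row.names = NULL
  )
}
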