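#' Coefficients of the linear-plus-Gompertz growth law
#'
#' The growth law for relative elongation is
#' \deqn{y(t) = A t + B + C \exp(-\exp(-D (t - t_e)))}
#' where `A` (s^-1) is the slope of the linear start-up region, `B` collects
#' the slowly varying constants, `C` is the dimensionless growth amplitude,
#' `D` (s^-1) equals the diffusion/reduction rate constant k2 of the
#' wall-loosening-factor kinetics, and `t_e` (s) is the effective time at
#' which the supplied growth factor starts to dominate (the inflection point
#' of the sigmoid).
#'
#' @param A,B,C,D,t_e Coefficient values (see Description for units).
#' @param se Optional named numeric vector of standard errors
#'   (`A`, `B`, `C`, `D`, `t_e`); defaults to `NA`.
#' @param rss Residual sum of squares of the fit that produced the
#'   coefficients, if any.
#' @return An object of class `fit_params`.
#' @examples
#' p <- fit_params(A = 15.4e-7, B = 0.0009, C = 0.083, D = 12.9e-5,
#'                 t_e = 22205)
#' relative_elongation(36000, p)
#' @export
fit_params <- function(A, B, C, D, t_e, se = NULL, rss = NA_real_) {
  A <- unname(A); B <- unname(B); C <- unname(C)
  D <- unname(D); t_e <- unname(t_e)
  vals <- c(A = A, B = B, C = C, D = D, t_e = t_e)
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("all five coefficients must be finite", call. = FALSE)
  if (D <= 0) stop("`D` must be positive (it equals the rate k2)",
                   call. = FALSE)
  if (C < 0) stop("`C` (growth amplitude) must be non-negative", call. = FALSE)
  se_full <- c(A = NA_real_, B = NA_real_, C = NA_real_, D = NA_real_,
               t_e = NA_real_)
  if (!is.null(se)) {
    se <- se[names(se) %in% names(se_full)]
    if (any(se < 0, na.rm = TRUE))
      stop("standard errors must be non-negative", call. = FALSE)
    se_full[names(se)] <- se
  }
  structure(list(A = A, B = B, C = C, D = D, t_e = t_e,
                 se = se_full, rss = rss),
            class = "fit_params")
}

#' @export
print.fit_params <- function(x, ...) {
  cat("<fit_params>\n")
  for (nm in c("A", "B", "C", "D", "t_e"))
    cat(sprintf("  %-3s = %.6g%s\n", nm, x[[nm]],
                if (is.finite(x$se[nm])) sprintf(" +/- %.3g", x$se[nm]) else ""))
  if (is.finite(x$rss)) cat(sprintf("  rss = %.3g\n", x$rss))
  invisible(x)
}

as_fit_params <- function(p) {
  if (inherits(p, "fit_params")) return(p)
  if (is.numeric(p) && all(c("A", "B", "C", "D", "t_e") %in% names(p)))
    return(fit_params(p[["A"]], p[["B"]], p[["C"]], p[["D"]], p[["t_e"]]))
  stop("cannot interpret `p` as fit_params", call. = FALSE)
}

#' Growth-factor concentration under production/decay kinetics
#'
#' Closed-form solution of the wall-loosening-factor balance
#' \eqn{dn/dt = k_1 - k_2 n}: production at constant rate `k1`
#' (concentration s^-1) and first-order reduction (diffusion into the wall,
#' inactivation) at rate `k2` (s^-1),
#' \deqn{n(t) = k_1/k_2 + (n_0 - k_1/k_2) e^{-k_2 t}.}
#' The growth regime assumed downstream has the biosynthesis time constant
#' much longer than the reduction one (`T1 = 1/k1 >> T2 = 1/k2 > 0`).
#'
#' @param t Time (s), non-negative.
#' @param k1 Production rate (concentration s^-1).
#' @param k2 Reduction rate (s^-1), positive.
#' @param n0 Initial concentration at `t = 0`.
#' @return Concentration `n(t)` (same arbitrary units as `n0`).
#' @examples
#' factor_concentration(10, k1 = 1, k2 = 0.1, n0 = 0)
#' @export
factor_concentration <- function(t, k1, k2, n0) {
  if (!is.finite(k2) || k2 <= 0)
    stop("`k2` must be positive", call. = FALSE)
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  nss <- k1 / k2
  nss + (n0 - nss) * exp(-k2 * t)
}

#' Evaluate the growth law
#'
#' Forward model \eqn{y(t) = A t + B + C e^{-e^{-D (t - t_e)}}} for
#' dimensionless relative elongation `(V(t) - V0)/V0` with time in seconds.
#'
#' @param t Time (s); vectorised.
#' @param p A [fit_params()] object (or named vector with `A`..`t_e`).
#' @return Relative elongation (dimensionless).
#' @export
relative_elongation <- function(t, p) {
  p <- as_fit_params(p)
  p$A * t + p$B + p$C * exp(-exp(-p$D * (t - p$t_e)))
}

#' Early-epoch (biosynthesis-limited) approximation
#'
#' When biosynthesis is the limiting mechanism the growth law linearises to
#' \deqn{y(t) \approx \bar\Phi_0 t + \bar\Phi_0 t^2 / (2 T_1)}
#' with \eqn{\bar\Phi_0 = \Phi_0 (P - Y) n_0} the effective
#' extensibility-turgor product and `T1` the (long) biosynthesis time
#' constant.
#'
#' @param t Time (s), non-negative.
#' @param phibar0 Effective rate \eqn{\bar\Phi_0} (s^-1).
#' @param T1 Biosynthesis time constant (s), positive.
#' @return Relative elongation (dimensionless).
#' @export
epoch1_approx <- function(t, phibar0, T1) {
  if (!is.finite(T1) || T1 <= 0) stop("`T1` must be positive", call. = FALSE)
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  phibar0 * t + phibar0 * t^2 / (2 * T1)
}

#' Late-epoch (diffusion-dominated) approximation
#'
#' When the diffusion mechanism dominates, the growth law reduces to the
#' Gompertz sigmoid \eqn{C e^{-e^{-D (t - t_e)}} + B}. The derivation's
#' constant prefactor and the `exp(D t_e)`-style nesting factor are absorbed
#' into the fitted `C` and `t_e`; the additive constant is identified with
#' the single fitted `B`.
#'
#' @inheritParams relative_elongation
#' @return Relative elongation (dimensionless).
#' @export
epoch2_approx <- function(t, p) {
  p <- as_fit_params(p)
  p$C * exp(-exp(-p$D * (t - p$t_e))) + p$B
}

#' Analytic growth rate of the growth law
#'
#' The time derivative of [relative_elongation()]:
#' \deqn{y'(t) = C D \exp[-\exp(-D (t - t_e)) - D (t - t_e)] (+ A).}
#' The sigmoid part attains its maximum exactly at `t = t_e` with value
#' `C * D / e`.
#'
#' @inheritParams relative_elongation
#' @param include_linear If `TRUE`, adds the linear-region slope `A`.
#' @return Rate (s^-1).
#' @export
growth_rate <- function(t, p, include_linear = FALSE) {
  p <- as_fit_params(p)
  z <- -p$D * (t - p$t_e)
  r <- p$C * p$D * exp(-exp(z) + z)
  if (include_linear) r <- r + p$A
  r
}

#' Derive kinetic and turgor quantities from fitted coefficients
#'
#' Maps the fitted coefficients onto the kinetics: `k2 = D` (s^-1),
#' `T2 = 1/D` (s), \eqn{\bar\Phi_0 = A / n_0} (s^-1), and a turgor-pressure
#' proxy `A / (Phi0 * n0)` on a proportional MPa scale (`Phi0` is the
#' Lockhart extensibility constant, 1e-6 MPa^-1 s^-1 by default). Since the
#' growth-factor concentration scale `n0` is not observable, `n0` is
#' normalised to 1 by default and all derived quantities are proportional in
#' it. Standard errors propagate by first-order total derivatives
#' (`se_k2 = se_D`, `se_T2 = se_D / D^2`, `se_phibar0 = se_A / n0`).
#'
#' @param p A [fit_params()] with `D > 0`.
#' @param phi0 Lockhart constant (MPa^-1 s^-1).
#' @param n0 Initial growth-factor concentration (normalisation).
#' @return A list of class `kinetic_quantities` with elements `k2`, `T2`,
#'   `phibar0`, `turgor_proxy` and their `se_*` where the fit provided
#'   standard errors. `k2 * T2 == 1` exactly.
#' @examples
#' p <- fit_params(A = 15.4e-7, B = 0.0009, C = 0.083, D = 12.9e-5,
#'                 t_e = 22205)
#' derive_kinetics(p)
#' @export
derive_kinetics <- function(p, phi0 = 1e-6, n0 = 1) {
  p <- as_fit_params(p)
  if (p$D <= 0) stop("invalid fit: `D` must be positive", call. = FALSE)
  if (phi0 <= 0 || n0 <= 0)
    stop("`phi0` and `n0` must be positive", call. = FALSE)
  out <- list(
    k2 = p$D,
    T2 = 1 / p$D,
    phi0 = phi0,
    phibar0 = p$A / n0,
    turgor_proxy = p$A / (phi0 * n0),
    se_k2 = p$se[["D"]],
    se_T2 = if (is.finite(p$se[["D"]])) p$se[["D"]] / p$D^2 else NA_real_,
    se_phibar0 = if (is.finite(p$se[["A"]])) p$se[["A"]] / n0 else NA_real_,
    se_turgor_proxy = if (is.finite(p$se[["A"]]))
      p$se[["A"]] / (phi0 * n0) else NA_real_
  )
  class(out) <- "kinetic_quantities"
  out
}

#' @export
print.kinetic_quantities <- function(x, ...) {
  cat(sprintf("<kinetic_quantities> k2 = %.4g /s, T2 = %.4g s, phibar0 = %.4g /s, turgor proxy = %.4g\n",
              x$k2, x$T2, x$phibar0, x$turgor_proxy))
  invisible(x)
}
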