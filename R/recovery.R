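#' Seeded parameter-recovery simulation study
#'
#' Draws growth-law coefficient sets uniformly from the ranges spanned by
#' published coleoptile fits (`A` in [0, 3e-6] s^-1, `B` in [-0.006, 0.01],
#' `C` in [0.03, 0.33], `D` in [9e-5, 5.5e-4] s^-1, `t_e` in [9800, 24700]
#' s), simulates each curve with Gaussian noise of `noise_frac * C` over a
#' record spanning `[0, t_e + 6/D]` (long enough for the sigmoid to
#' saturate, as an experiment would be run) at `n_points` samples, refits
#' it, and tabulates the relative recovery errors.
#'
#' @param n_rep Number of replicates.
#' @param seed Integer seed driving both the parameter draws and the noise.
#' @param noise_frac Noise SD as a fraction of the amplitude `C`.
#' @param n_points Samples per simulated record.
#' @return A data frame with one row per replicate: the true coefficients,
#'   `converged`, and relative errors `rel_A` ... `rel_t_e` (`NA` for
#'   failed fits).
#' @export
parameter_recovery_study <- function(n_rep = 200L, seed = 1L,
                                     noise_frac = 0.005, n_points = 600L) {
  draws <- with_seed(seed, data.frame(
    A = stats::runif(n_rep, 0, 3e-6),
    B = stats::runif(n_rep, -0.006, 0.01),
    C = stats::runif(n_rep, 0.03, 0.33),
    D = stats::runif(n_rep, 9e-5, 5.5e-4),
    t_e = stats::runif(n_rep, 9800, 24700),
    noise_seed = sample.int(2^30, n_rep)
  ))
  rows <- lapply(seq_len(n_rep), function(i) {
    tr <- fit_params(draws$A[i], draws$B[i], draws$C[i], draws$D[i],
                     draws$t_e[i])
    span <- draws$t_e[i] + 6 / draws$D[i]
    ts <- make_growth_curve(tr, dt = span / (n_points - 1), span = span,
                            noise_sd = noise_frac * draws$C[i],
                            seed = draws$noise_seed[i])
    f <- tryCatch(fit_growth(ts, seed = draws$noise_seed[i]),
                  error = function(e) NULL)
    if (is.null(f))
      return(data.frame(draws[i, 1:5], converged = FALSE, rel_A = NA_real_,
                        rel_B = NA_real_, rel_C = NA_real_, rel_D = NA_real_,
                        rel_t_e = NA_real_))
    p <- f$params
    rel <- function(nm) abs(p[[nm]] - tr[[nm]]) /
      max(abs(tr[[nm]]), .Machine$double.eps)
    data.frame(draws[i, 1:5], converged = TRUE,
               rel_A = rel("A"), rel_B = rel("B"), rel_C = rel("C"),
               rel_D = rel("D"), rel_t_e = rel("t_e"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
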