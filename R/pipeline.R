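#' End-to-end analysis pipeline
#'
#' Chains the package's stages over a configuration list: growth-law fit of
#' the elongation record, derived kinetic quantities, growth-rate power
#' spectrum with its zero-frequency intensity, pH x elongation
#' cross-correlation with the derivative-jump H+ estimate, and (when
#' electrophysiological inputs are given) the E_H+ table. Every option that
#' affects a number, plus the seed, is echoed into the returned manifest; a
#' failing stage aborts with the stage name while partial results are kept
#' in the error condition.
#'
#' @param config A list with any of:
#'   \describe{
#'     \item{elongation}{path to a `time,value` CSV or a `growth_ts`
#'       (kind `relative_elongation` or `elongation`).}
#'     \item{time_unit}{unit of the CSV time column (`"s"`, `"min"`, `"h"`).}
#'     \item{L0}{initial length (um) to convert `elongation` records to
#'       relative elongation.}
#'     \item{ph}{path/`growth_ts` of a pH trace (enables the
#'       cross-correlation stage, paired with the elongation record).}
#'     \item{detrend}{spectrum detrend mode (default `"model"` when a fit is
#'       available, else `"mean"`).}
#'     \item{max_lag, jump_window}{cross-correlation options.}
#'     \item{em_table}{matrix/data frame of E_H+ ratio cells for
#'       [aggregate_ehplus()].}
#'     \item{seed}{integer seed used by every stochastic step (default 1).}
#'     \item{out_dir}{optional directory; when set, stage outputs are
#'       written as commented CSVs.}
#'   }
#' @return A list of class `fitexex_pipeline` with elements `fit`,
#'   `kinetics`, `coefficients` (one-row table), `spectrum`,
#'   `zero_intensity`, `xcorr`, `ehplus` (those that ran) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  manifest <- list(package_version = as.character(utils::packageVersion("fitexex")),
                   seed = seed,
                   time_unit = config$time_unit %||% "s",
                   detrend = config$detrend %||% "model",
                   max_lag = config$max_lag,
                   jump_window = config$jump_window %||% 5L,
                   L0 = config$L0)
  out <- list(manifest = manifest)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  load_series <- function(x, kind) {
    if (inherits(x, "growth_ts")) return(x)
    if (is.character(x)) {
      if (!file.exists(x))
        stop(sprintf("input file not found: '%s'", x), call. = FALSE)
      return(read_growth_csv(x, kind = kind,
                             time_unit = manifest$time_unit))
    }
    stop("inputs must be growth_ts objects or CSV paths", call. = FALSE)
  }

  elong <- NULL
  if (!is.null(config$elongation)) {
    elong <- stage("load", load_series(config$elongation,
                                       config$elongation_kind %||%
                                         "relative_elongation"))
    if (elong$kind == "elongation") {
      if (is.null(config$L0))
        stop("pipeline stage 'load' failed: `L0` is required to convert an elongation record",
             call. = FALSE)
      rel <- to_relative_elongation(elong, config$L0)
    } else rel <- elong

    out$fit <- stage("fit", fit_growth(rel, seed = seed))
    out$kinetics <- stage("kinetics", derive_kinetics(out$fit$params))
    p <- out$fit$params
    out$coefficients <- data.frame(
      label = rel$label, A = p$A, se_A = p$se[["A"]], B = p$B,
      se_B = p$se[["B"]], C = p$C, se_C = p$se[["C"]], D = p$D,
      se_D = p$se[["D"]], t_e = p$t_e, se_t_e = p$se[["t_e"]],
      k2 = out$kinetics$k2, T2 = out$kinetics$T2,
      turgor_proxy = out$kinetics$turgor_proxy)

    rate <- stage("rate", differentiate(rel))
    detrend <- manifest$detrend
    out$spectrum <- stage("spectrum",
                          power_spectrum(resample_uniform(rate),
                                         detrend = detrend,
                                         model_params = p))
    out$zero_intensity <- zero_frequency_intensity(out$spectrum)
  }

  if (!is.null(config$ph) && !is.null(elong)) {
    ph <- stage("xcorr", load_series(config$ph, "pH"))
    r <- stage("xcorr", cross_correlate(ph, elong,
                                        max_lag = config$max_lag))
    r <- ccf_derivative(r)
    out$xcorr <- stage("xcorr", jump_at_zero(r,
                                             window = manifest$jump_window,
                                             seed = seed))
  }

  if (!is.null(config$em_table))
    out$ehplus <- stage("ehplus", aggregate_ehplus(config$em_table))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- sprintf("fitexex %s seed=%d", manifest$package_version, seed)
    if (!is.null(out$coefficients))
      utils::write.csv(out$coefficients,
                       file.path(config$out_dir, "coefficients.csv"),
                       row.names = FALSE)
    if (!is.null(out$spectrum))
      utils::write.csv(data.frame(frequency_hz = out$spectrum$f,
                                  power = out$spectrum$p),
                       file.path(config$out_dir, "spectrum.csv"),
                       row.names = FALSE)
    if (!is.null(out$xcorr))
      utils::write.csv(data.frame(lag_s = out$xcorr$lags,
                                  ccf = out$xcorr$ccf,
                                  dccf = out$xcorr$dccf),
                       file.path(config$out_dir, "xcorr.csv"),
                       row.names = FALSE)
    writeLines(c(hdr, paste(names(manifest),
                            vapply(manifest, function(v)
                              paste(format(v), collapse = ","), ""),
                            sep = "=")),
               file.path(config$out_dir, "manifest.txt"))
  }

  class(out) <- "fitexex_pipeline"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fitexex_pipeline <- function(x, ...) {
  cat("<fitexex_pipeline>\n")
  if (!is.null(x$fit)) print(x$fit$params)
  if (!is.null(x$zero_intensity))
    cat(sprintf("  f=0 intensity: %.4g\n", x$zero_intensity))
  if (!is.null(x$xcorr))
    cat(sprintf("  lag_max = %g s, jump0 = %.4g\n",
                x$xcorr$lag_max, x$xcorr$jump0))
  if (!is.null(x$ehplus))
    cat(sprintf("  E_H+ grand mean = %.3f mV/um\n", x$ehplus$grand_mean))
  invisible(x)
}
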