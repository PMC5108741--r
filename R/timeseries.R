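#' Time-series container for elongation, growth-rate and pH records
#'
#' All analyses in this package operate on uniformly (or near-uniformly)
#' sampled `(time, value)` records with a declared kind. Time is always kept
#' in seconds internally; minute- or hour-stamped inputs are converted at the
#' I/O boundary.
#'
#' @param t Numeric vector of sample times, strictly increasing (seconds
#'   after conversion).
#' @param y Numeric vector of values, same length as `t`. Dimensionless for
#'   `relative_elongation`, micrometres for `elongation`, s^-1 (or um/s) for
#'   `rate`, pH units for `pH`.
#' @param kind One of `"elongation"`, `"relative_elongation"`, `"rate"`,
#'   `"pH"`.
#' @param label Free-text treatment tag carried through to summary tables.
#' @param time_unit Unit of the supplied `t` (`"s"`, `"min"` or `"h"`);
#'   converted to seconds on construction.
#'
#' @return An object of class `growth_ts`: a list with elements `t`, `y`,
#'   `kind`, `label`.
#' @examples
#' ts <- growth_ts(0:10, (0:10) * 2e-6, kind = "relative_elongation")
#' @export
growth_ts <- function(t, y, kind = c("relative_elongation", "elongation",
                                     "rate", "pH"),
                      label = "", time_unit = c("s", "min", "h")) {
  kind <- match.arg(kind)
  time_unit <- match.arg(time_unit)
  t <- as.numeric(t)
  y <- as.numeric(y)
  if (length(t) != length(y))
    stop("`t` and `y` must have equal length", call. = FALSE)
  if (length(t) < 2L)
    stop("a growth_ts needs at least 2 samples", call. = FALSE)
  if (anyNA(t) || anyNA(y))
    stop("missing values must be removed before constructing a growth_ts",
         call. = FALSE)
  if (any(diff(t) <= 0))
    stop("`t` must be strictly increasing (reversed or duplicated time stamps)",
         call. = FALSE)
  t <- t * switch(time_unit, s = 1, min = 60, h = 3600)
  structure(list(t = t, y = y, kind = kind, label = as.character(label)[1]),
            class = "growth_ts")
}

#' @export
print.growth_ts <- function(x, ...) {
  cat(sprintf("<growth_ts> kind=%s n=%d span=[%g, %g] s%s\n",
              x$kind, length(x$t), x$t[1], x$t[length(x$t)],
              if (nzchar(x$label)) paste0(" label=", x$label) else ""))
  invisible(x)
}

#' @export
length.growth_ts <- function(x) length(x$t)

#' @export
as.data.frame.growth_ts <- function(x, ...) {
  data.frame(time = x$t, value = x$y)
}

ts_dt <- function(x) {
  d <- diff(x$t)
  mean(d)
}

ts_is_uniform <- function(x, tol = 0.01) {
  d <- diff(x$t)
  (max(d) - min(d)) <= tol * mean(d)
}

stopifnot_kind <- function(x, kinds) {
  if (!inherits(x, "growth_ts"))
    stop("expected a growth_ts object", call. = FALSE)
  if (!x$kind %in% kinds)
    stop(sprintf("expected a series of kind %s, got '%s'",
                 paste(sQuote(kinds), collapse = " or "), x$kind),
         call. = FALSE)
  invisible(x)
}

#' Read a time-series CSV
#'
#' Expects the two-column dialect `time,value` (comma-separated, UTF-8, with
#' header); an optional third column `series` splits the file into replicate
#' records. Rows with missing values are dropped.
#'
#' @param path Path to the CSV file.
#' @param kind Declared kind of the record (see [growth_ts()]).
#' @param time_unit Unit of the `time` column; converted to seconds.
#' @param label Label used when the file holds a single series.
#' @return A `growth_ts`, or a list of them when a `series` column is present.
#' @export
read_growth_csv <- function(path, kind = "relative_elongation",
                            time_unit = "s", label = "") {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("time", "value") %in% names(df)))
    stop(sprintf("'%s' must have columns 'time' and 'value'", path),
         call. = FALSE)
  df <- df[stats::complete.cases(df[c("time", "value")]), , drop = FALSE]
  if ("series" %in% names(df)) {
    out <- lapply(split(df, df$series), function(d) {
      d <- d[order(d$time), , drop = FALSE]
      growth_ts(d$time, d$value, kind = kind, label = d$series[1],
                time_unit = time_unit)
    })
    return(out)
  }
  df <- df[order(df$time), , drop = FALSE]
  growth_ts(df$time, df$value, kind = kind, label = label,
            time_unit = time_unit)
}

#' Write a time-series CSV
#'
#' @param x A `growth_ts`.
#' @param path Output path.
#' @param header Optional comment lines (prefixed with `#`) describing units
#'   and options; reproducibility metadata goes here.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(x, path, header = character()) {
  stopifnot(inherits(x, "growth_ts"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header))
    writeLines(paste0("# ", header), con)
  writeLines(sprintf("# kind: %s; time unit: s", x$kind), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' Convert an elongation record (micrometres) to relative elongation
#'
#' Relative elongation is `(u - u[1]) / L0`, the dimensionless quantity the
#' growth law is fitted to; `L0` is the initial segment length in the same
#' units as `u`.
#'
#' @param x A `growth_ts` of kind `elongation`.
#' @param L0 Initial length (um); must be positive.
#' @return A `growth_ts` of kind `relative_elongation`.
#' @export
to_relative_elongation <- function(x, L0) {
  stopifnot_kind(x, "elongation")
  if (!is.finite(L0) || L0 <= 0)
    stop("`L0` must be a positive length in the units of `x`", call. = FALSE)
  growth_ts(x$t, (x$y - x$y[1]) / L0, kind = "relative_elongation",
            label = x$label)
}

#' Resample a series onto a uniform grid by linear interpolation
#'
#' @param x A `growth_ts`.
#' @param dt Target sampling interval (s); defaults to the mean interval.
#' @return A `growth_ts` on the uniform grid, same kind.
#' @export
resample_uniform <- function(x, dt = NULL) {
  stopifnot(inherits(x, "growth_ts"))
  if (is.null(dt)) dt <- ts_dt(x)
  grid <- seq(x$t[1], x$t[length(x$t)], by = dt)
  yi <- stats::approx(x$t, x$y, xout = grid)$y
  growth_ts(grid, yi, kind = x$kind, label = x$label)
}
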