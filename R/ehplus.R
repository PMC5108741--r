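#' E_H+ ratio of membrane potential to the pH x elongation product
#'
#' The empirical constant \eqn{E_{H+} = E_m / (\mathrm{pH} \cdot u)} links
#' the membrane potential `E_m` (mV) of parenchymal coleoptile cells to the
#' product of medium pH (`pH = log10(1/a_H+)`) and elongation `u` (um).
#' Because mV/um and V/mm differ by a factor of exactly 1, the ratio is
#' numerically identical in both conventions. Cells computed from measured
#' potentials are negative (the sign of `E_m`); the headline constant is
#' usually quoted as the magnitude.
#'
#' @param em Membrane potential (mV).
#' @param ph Medium pH (> 0).
#' @param u Elongation (um, > 0). Whether `u` is a cumulative elongation or
#'   a per-interval increment is a convention of the data set; the ratio is
#'   computed for whatever value is supplied.
#' @return `em / (ph * u)` in mV/um (= V/mm); vectorised.
#' @examples
#' ehplus_ratio(-157, 5, 200)  # -0.157
#' @export
ehplus_ratio <- function(em, ph, u) {
  if (any(!is.finite(ph)) || any(ph <= 0))
    stop("`ph` must be positive", call. = FALSE)
  if (any(!is.finite(u)) || any(u <= 0))
    stop("`u` must be positive", call. = FALSE)
  em / (ph * u)
}

#' Predict the membrane potential from growth and pH alone
#'
#' Inverts [ehplus_ratio()]: once `E_H+` is calibrated, the membrane
#' potential can be obtained from growth and pH measurements without
#' electrophysiology, `E_m = E_H+ * pH * u`.
#'
#' @param ehplus Calibrated constant (mV/um, sign included).
#' @param ph Medium pH (> 0).
#' @param u Elongation (um, > 0; a zero elongation degenerately predicts
#'   0 mV and is rejected).
#' @return Predicted `E_m` (mV).
#' @examples
#' predict_em(-0.157, 5, 200)  # -157 mV
#' @export
predict_em <- function(ehplus, ph, u) {
  if (any(!is.finite(ehplus))) stop("`ehplus` must be finite", call. = FALSE)
  if (any(!is.finite(ph)) || any(ph <= 0))
    stop("`ph` must be positive", call. = FALSE)
  if (any(!is.finite(u)) || any(u <= 0))
    stop("`u` must be positive (u = 0 degenerately predicts 0 mV)",
         call. = FALSE)
  ehplus * ph * u
}

#' Aggregate an E_H+ ratio matrix with row, column and grand means
#'
#' Takes a complete treatments x time-points matrix of E_H+ ratios and
#' appends the margins of the published table layout: per-treatment (row)
#' means over time points, per-time-point (column) means over treatments,
#' and the grand mean computed as the mean of the row means (equal, for a
#' complete table, to the mean of the column means and of all cells).
#' Sample SDs accompany every margin. Because the grand-mean uncertainty can
#' be quoted in several inequivalent ways, three are reported side by side:
#' the SD of the row means, the SD of the column means, and the mean of the
#' per-row SDs.
#'
#' @param cells Numeric matrix (or data frame) of ratios, rows = treatments,
#'   columns = time points; `dimnames` are carried through. Must be complete
#'   (no `NA`) and rectangular.
#' @return A list of class `ehplus_table`: `cells`, `row_means`, `row_sds`,
#'   `col_means`, `col_sds`, `grand_mean`, `grand_sd_rows`, `grand_sd_cols`,
#'   `grand_mean_row_sds`.
#' @examples
#' m <- rbind(c(-0.199, -0.200, -0.192), c(-0.182, -0.177, -0.175))
#' aggregate_ehplus(m)$grand_mean
#' @export
aggregate_ehplus <- function(cells) {
  m <- as.matrix(cells)
  if (!is.numeric(m)) stop("`cells` must be numeric", call. = FALSE)
  if (anyNA(m))
    stop("ragged/incomplete matrix: every cell must be present", call. = FALSE)
  if (nrow(m) < 1L || ncol(m) < 2L)
    stop("need at least 1 treatment and 2 time points", call. = FALSE)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  row_sds <- apply(m, 1, stats::sd)
  col_sds <- apply(m, 2, stats::sd)
  structure(list(cells = m,
                 row_means = row_means, row_sds = row_sds,
                 col_means = col_means, col_sds = col_sds,
                 grand_mean = mean(row_means),
                 grand_sd_rows = stats::sd(row_means),
                 grand_sd_cols = stats::sd(col_means),
                 grand_mean_row_sds = mean(row_sds)),
            class = "ehplus_table")
}

#' @export
print.ehplus_table <- function(x, ...) {
  out <- cbind(x$cells, Mean = x$row_means)
  out <- rbind(out, Mean = c(x$col_means, x$grand_mean))
  print(round(out, 3))
  cat(sprintf("grand mean %.3f (SD of row means %.3f, of column means %.3f, mean row SD %.3f)\n",
              x$grand_mean, x$grand_sd_rows, x$grand_sd_cols,
              x$grand_mean_row_sds))
  invisible(x)
}

#' Bundled E_H+ ratio matrix for maize coleoptile treatments
#'
#' Loads the packaged 4-treatment x 6-time-point matrix of measured
#' E_m / (pH * u) ratios (mV/um) for maize coleoptile segments under KCl /
#' IAA / A-9-C treatments, the worked example for [aggregate_ehplus()].
#'
#' @return A numeric matrix with treatment row names and time-point (min)
#'   column names.
#' @export
ehplus_example_matrix <- function() {
  path <- system.file("extdata", "ehplus_ratios.csv", package = "fitexex",
                      mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Bundled control growth-law coefficients for maize coleoptile
#'
#' Loads the packaged pair of control fits (coefficients with standard
#' errors) for maize coleoptile relative elongation under constant dim green
#' light at 25 C, the worked example for [aggregate_fits()].
#'
#' @return A data frame with columns `source`, `A`, `se_A`, ..., `t_e`,
#'   `se_t_e`.
#' @export
control_coefficients <- function() {
  path <- system.file("extdata", "control_fit_coefficients.csv",
                      package = "fitexex", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#")
}
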