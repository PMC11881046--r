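# The ten-metric quality suite for one method's potentials vs experiment.
#
# Error metrics are in volts with the calculated-minus-experimental sign
# convention. "Trimmed" (tr) variants remove the systematic error (the MSE)
# before measuring, so they score relative potentials only.

check_paired <- function(calc, exp, min_n = 2L) {
  if (length(calc) != length(exp)) {
    stop("calc and exp must have equal length (", length(calc),
         " vs ", length(exp), ")")
  }
  if (length(calc) < min_n) stop("need at least ", min_n, " paired values")
  if (!all(is.finite(calc)) || !all(is.finite(exp))) stop("non-finite input")
  invisible(TRUE)
}

#' Mean signed error
#'
#' `mean(calc - exp)`: the systematic (absolute-scale) error of a method.
#'
#' @param calc,exp calculated and experimental potentials, V, equal length.
#' @return MSE in volts.
#' @export
mse <- function(calc, exp) {
  check_paired(calc, exp)
  mean(calc - exp)
}

#' Mean and maximum absolute deviation
#'
#' `mad()` is the mean of `|calc - exp|`, `max_abs()` the largest single
#' deviation. Note this benchmark-domain `mad()` (mean absolute deviation
#' from experiment) masks [stats::mad()] (median absolute deviation) when
#' the package is attached.
#'
#' @param calc,exp calculated and experimental potentials, V, equal length.
#' @return Deviation in volts.
#' @export
mad <- function(calc, exp) {
  check_paired(calc, exp)
  mean(abs(calc - exp))
}

#' @rdname mad
#' @export
max_abs <- function(calc, exp) {
  check_paired(calc, exp)
  max(abs(calc - exp))
}

#' Trimmed deviations: MAD and MAX after removing the systematic error
#'
#' The MSE is subtracted from all predictions before taking the mean
#' (`madtr`) or maximum (`maxtr`) absolute residual. Both are invariant to
#' any constant shift of `calc`, so they measure relative-potential
#' accuracy.
#'
#' @param calc,exp calculated and experimental potentials, V, equal length.
#' @return Deviation in volts.
#' @export
madtr <- function(calc, exp) {
  check_paired(calc, exp)
  mad(calc - mse(calc, exp), exp)
}

#' @rdname madtr
#' @export
maxtr <- function(calc, exp) {
  check_paired(calc, exp)
  max_abs(calc - mse(calc, exp), exp)
}

#' Range of calculated potentials and its deviation from experiment
#'
#' `range_calc()` is the spread `max(calc) - min(calc)`. `rel_range()` is
#' the absolute deviation of that spread from the experimental range, so
#' over- and under-spread predictions are penalised alike.
#'
#' @param calc calculated potentials, V, length >= 2.
#' @param exp_range experimental range in volts (max - min over the
#'   reference set).
#' @return Volts.
#' @export
range_calc <- function(calc) {
  if (length(calc) < 2L) stop("need at least 2 values")
  if (!all(is.finite(calc))) stop("non-finite input")
  max(calc) - min(calc)
}

#' @rdname range_calc
#' @export
rel_range <- function(calc, exp_range) {
  stopifnot(is.numeric(exp_range), length(exp_range) == 1L, is.finite(exp_range))
  abs(range_calc(calc) - exp_range)
}

#' Calibration slope and squared correlation
#'
#' Ordinary least-squares slope of `calc` (response) on `exp` (predictor) -
#' the slope of the calibration line in a calculated-versus-experimental
#' plot - and the squared Pearson correlation. For a constant `calc` the
#' correlation is undefined; both slope and R-squared are returned as 0 by
#' convention (no predictive power).
#'
#' @param calc,exp calculated and experimental potentials, V, length >= 3;
#'   `exp` must not be constant.
#' @return A list with elements `slope` and `r2`.
#' @export
slope_r2 <- function(calc, exp) {
  check_paired(calc, exp, min_n = 3L)
  vx <- sum((exp - mean(exp))^2)
  if (vx == 0) stop("degenerate experimental set (all values equal)")
  sxy <- sum((exp - mean(exp)) * (calc - mean(calc)))
  k <- sxy / vx
  vy <- sum((calc - mean(calc))^2)
  r2 <- if (vy == 0) 0 else sxy^2 / (vx * vy)
  list(slope = k, r2 = r2)
}

#' Symmetric slope penalty
#'
#' Re-expresses a calibration slope `k` so over- and under-scaling are
#' penalised alike: `1 - 1/k` for `k >= 1`, `1 - k` for `0 < k < 1`. The
#' ideal slope 1 maps to 0, and `rel_slope(k) == rel_slope(1/k)` for all
#' positive `k`. Non-positive slopes (anti-correlated or flat predictions)
#' map to the worst score, 1.
#'
#' @param k calibration slope(s), finite.
#' @return Penalty in `[0, 1]`; 0 is ideal.
#' @export
#' @examples
#' rel_slope(c(0.5, 1, 2)) # 0.5 0 0.5
rel_slope <- function(k) {
  if (!all(is.finite(k))) stop("non-finite slope")
  ifelse(k >= 1, 1 - 1 / k, ifelse(k > 0, 1 - k, 1))
}

#' Rank correlations: Spearman's rho and Kendall's tau
#'
#' `spearman_rho()` correlates average-rank vectors; `kendall_tau()` is the
#' tau-b statistic over all `n(n-1)/2` site pairs (66 pairs for the
#' 12-protein reference), with the standard tie correction. Both are
#' invariant under strictly monotone transforms of `calc`.
#'
#' @param calc,exp calculated and experimental potentials, equal length >= 2.
#' @return Correlation in `[-1, 1]`; `NA` if either vector is constant.
#' @export
spearman_rho <- function(calc, exp) {
  check_paired(calc, exp)
  suppressWarnings(stats::cor(calc, exp, method = "spearman"))
}

#' @rdname spearman_rho
#' @export
kendall_tau <- function(calc, exp) {
  check_paired(calc, exp)
  suppressWarnings(stats::cor(calc, exp, method = "kendall"))
}

#' Full quality-measure vector for one method
#'
#' Evaluates all ten quality measures plus the two penalty transforms
#' against the experimental set: MSE, MAD, MAX, MADtr, MAXtr, range and
#' Rel Range, slope and Rel Slope, R-squared, Spearman's rho, Kendall's tau.
#'
#' For a constant `calc`, R-squared, rho, tau and slope are all reported as
#' 0 (the null-baseline convention; the correlations are undefined and the
#' predictor has no resolving power).
#'
#' @param calc,exp calculated and experimental potentials, V, same sites in
#'   the same order.
#' @param exp_range experimental range used by `rel_range`; defaults to
#'   `max(exp) - min(exp)`. Pass a number to pin an externally chosen
#'   constant instead.
#' @return A one-row tibble with columns `mse`, `mad`, `max_abs`, `madtr`,
#'   `maxtr`, `range_calc`, `rel_range`, `slope`, `rel_slope`, `r2`, `rho`,
#'   `tau`.
#' @export
#' @examples
#' ref <- bcp_reference()
#' metric_set(ref$e_exp - 0.5, ref$e_exp) # pure shift: madtr = 0, slope = 1
metric_set <- function(calc, exp, exp_range = NULL) {
  check_paired(calc, exp, min_n = 3L)
  if (is.null(exp_range)) exp_range <- max(exp) - min(exp)
  sr <- slope_r2(calc, exp)
  constant <- stats::var(calc) == 0
  rho <- if (constant) 0 else spearman_rho(calc, exp)
  tau <- if (constant) 0 else kendall_tau(calc, exp)
  tibble::tibble(
    mse = mse(calc, exp),
    mad = mad(calc, exp),
    max_abs = max_abs(calc, exp),
    madtr = madtr(calc, exp),
    maxtr = maxtr(calc, exp),
    range_calc = range_calc(calc),
    rel_range = rel_range(calc, exp_range),
    slope = sr$slope,
    rel_slope = rel_slope(sr$slope),
    r2 = sr$r2,
    rho = rho,
    tau = tau
  )
}

#' Quality measures for every method in a potential table
#'
#' Aligns each method's row to the reference sites by abbreviation and
#' computes its [metric_set()].
#'
#' @param table a [potential_table()] whose sites match `reference$abbr`.
#' @param reference experimental reference tibble (default
#'   [bcp_reference()]) with columns `abbr` and `e_exp`.
#' @param exp_range passed to [metric_set()]; `NULL` computes from the
#'   reference.
#' @return A tibble: `method_id` plus the twelve metric columns, one row
#'   per method.
#' @export
metric_table <- function(table, reference = bcp_reference(), exp_range = NULL) {
  stopifnot(inherits(table, "potential_table"))
  idx <- match(reference$abbr, table$sites)
  if (anyNA(idx)) {
    stop("potential table lacks reference site(s): ",
         paste(reference$abbr[is.na(idx)], collapse = ", "))
  }
  exp <- reference$e_exp
  rows <- lapply(seq_len(nrow(table$values)), function(i) {
    metric_set(table$values[i, idx], exp, exp_range = exp_range)
  })
  res <- dplyr::bind_rows(rows)
  res <- tibble::add_column(res, method_id = table$methods$method_id,
                            .before = 1L)
  res
}
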