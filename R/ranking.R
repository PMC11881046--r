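# Per-metric ranks, the six-metric composite rank, min-max normalized
# scores, and the constant-predictor null baseline.

#' The six metrics behind the composite rank
#'
#' MADtr and MAXtr reward small calculated ranges; R-squared and tau reward
#' large ones; Rel Range and Rel Slope anchor the magnitude to experiment.
#' Spearman's rho is left out of the composite because of its very high
#' correlation with tau.
#'
#' @return Character vector of metric column names.
#' @export
composite_metrics <- function() {
  c("madtr", "maxtr", "r2", "tau", "rel_range", "rel_slope")
}

# Orientation of each metric: is a smaller or a larger value better?
metric_orientation <- function(metric) {
  lower <- c("mad", "max_abs", "madtr", "maxtr", "rel_range", "rel_slope")
  higher <- c("r2", "rho", "tau")
  ifelse(metric %in% lower, "lower_better",
         ifelse(metric %in% higher, "higher_better", "target_zero"))
}

#' Rank methods under a metric's orientation
#'
#' Rank 1 is best. `lower_better` ranks ascending values, `higher_better`
#' descending, and `target_zero` ranks by absolute value (for signed
#' quantities like the MSE whose ideal is 0). Ties receive the average of
#' the tied positions, so each rank column sums to `M(M+1)/2`.
#'
#' Values are compared at 12 significant digits, so quantities that are
#' equal up to double-precision rounding noise (e.g. an R-squared of
#' `1 - 2e-16` against an exact 1) tie rather than being ordered by
#' floating-point jitter.
#'
#' @param values one metric across methods.
#' @param orientation `"lower_better"`, `"higher_better"` or
#'   `"target_zero"`.
#' @return Numeric rank vector.
#' @export
#' @examples
#' rank_by_metric(c(0.1, 0.3, 0.2), "lower_better") # 1 3 2
rank_by_metric <- function(values,
                           orientation = c("lower_better", "higher_better",
                                           "target_zero")) {
  orientation <- match.arg(orientation)
  if (length(values) < 1L) stop("need at least one value")
  key <- switch(orientation,
    lower_better = values,
    higher_better = -values,
    target_zero = abs(values)
  )
  rank(signif(key, 12), ties.method = "average")
}

#' Composite rank across the six selected quality metrics
#'
#' Each selected metric is ranked across methods under its orientation;
#' `avg6` is the mean of those ranks per method, and the composite rank is
#' the rank of `avg6` (ties averaged).
#'
#' @param metrics a metric tibble from [metric_table()] (one row per
#'   method, `method_id` column present and complete).
#' @param metric_selection metric columns to rank; defaults to
#'   [composite_metrics()].
#' @return A tibble: `method_id`, one `rank_<metric>` column per selected
#'   metric, `avg6`, `composite_rank`.
#' @export
composite_rank <- function(metrics, metric_selection = composite_metrics()) {
  metrics <- tibble::as_tibble(metrics)
  if (nrow(metrics) < 2L) stop("need at least 2 methods to rank")
  missing_cols <- setdiff(c("method_id", metric_selection), names(metrics))
  if (length(missing_cols) > 0L) {
    stop("metric table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  for (m in metric_selection) {
    if (!all(is.finite(metrics[[m]]))) {
      stop("incomplete metric '", m, "' for method(s): ",
           paste(metrics$method_id[!is.finite(metrics[[m]])], collapse = ", "))
    }
  }
  out <- tibble::tibble(method_id = metrics$method_id)
  for (m in metric_selection) {
    out[[paste0("rank_", m)]] <-
      rank_by_metric(metrics[[m]], metric_orientation(m))
  }
  rank_cols <- paste0("rank_", metric_selection)
  out$avg6 <- rowMeans(as.matrix(out[rank_cols]))
  out$composite_rank <- rank(out$avg6, ties.method = "average")
  out
}

#' Min-max normalized scores
#'
#' Each selected metric is rescaled over the method panel so 0 is the best
#' observed value and 1 the worst (orientation-aware); the total score per
#' method is the mean of its normalized values. A metric that is constant
#' across methods cannot discriminate and contributes 0 for everyone.
#'
#' Unlike the rank-based composite, this score is sensitive to the spread
#' of each metric: metrics with wide observed ranges (range, slope) are
#' de-emphasised relative to narrow ones (R-squared, tau), which is why the
#' two schemes can prefer different methods.
#'
#' @param metrics a metric tibble from [metric_table()].
#' @param metric_selection metric columns to score; defaults to
#'   [composite_metrics()], `"all"` selects all ten quality measures.
#' @return A tibble: `method_id`, one `score_<metric>` column per selected
#'   metric, `avg_score`.
#' @export
normalized_score <- function(metrics, metric_selection = composite_metrics()) {
  metrics <- tibble::as_tibble(metrics)
  if (identical(metric_selection, "all")) {
    # the ten quality measures, with range and slope entering through their
    # deviation transforms so that 0 remains the optimum for every column
    metric_selection <- c("mse", "mad", "max_abs", "madtr", "maxtr",
                          "rel_range", "rel_slope", "r2", "rho", "tau")
  }
  if (nrow(metrics) < 2L) stop("need at least 2 methods to score")
  out <- tibble::tibble(method_id = metrics$method_id)
  for (m in metric_selection) {
    v <- metrics[[m]]
    orient <- metric_orientation(m)
    if (orient == "target_zero") v <- abs(v)
    lo <- min(v); hi <- max(v)
    s <- if (hi == lo) rep(0, length(v)) else (v - lo) / (hi - lo)
    if (orient == "higher_better" && hi != lo) s <- 1 - s
    out[[paste0("score_", m)]] <- s
  }
  score_cols <- paste0("score_", metric_selection)
  out$avg_score <- rowMeans(as.matrix(out[score_cols]))
  out
}

#' Constant-predictor null baseline
#'
#' The weakest conceivable predictor assigns the same potential to every
#' site. Its trimmed deviations reduce to the spread of the experimental
#' values about their mean (MADtr is the mean absolute deviation of `exp`
#' from `mean(exp)`), and R-squared, rho, tau, slope and range are all 0 by
#' convention. For the bundled 12-site reference this gives MADtr of 0.17 V
#' and MAXtr of 0.36 V - the floor any real method should beat.
#'
#' @param exp experimental potentials, V.
#' @param value the constant prediction; defaults to `mean(exp)`, which
#'   zeroes the MSE. MADtr/MAXtr do not depend on this choice.
#' @param exp_range passed through to [metric_set()].
#' @return A one-row metric tibble with `method_id = "null"`.
#' @export
#' @examples
#' null_baseline(bcp_reference()$e_exp)[, c("madtr", "maxtr")]
null_baseline <- function(exp, value = mean(exp), exp_range = NULL) {
  stopifnot(length(exp) >= 2L, all(is.finite(exp)))
  if (is.null(exp_range)) exp_range <- max(exp) - min(exp)
  calc <- rep(value, length(exp))
  # Built directly rather than through metric_set(): the correlations and
  # slope of a constant predictor are undefined and fixed at 0 here, and a
  # degenerate (all-equal) experimental set must still yield the error rows.
  tibble::tibble(
    method_id = "null",
    mse = mse(calc, exp),
    mad = mad(calc, exp),
    max_abs = max_abs(calc, exp),
    madtr = madtr(calc, exp),
    maxtr = maxtr(calc, exp),
    range_calc = 0,
    rel_range = exp_range,
    slope = 0,
    rel_slope = 1, # a flat predictor carries the worst slope penalty
    r2 = 0,
    rho = 0,
    tau = 0
  )
}
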