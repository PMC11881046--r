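# Aggregate method performance across protocol factors and compare
# matched method pairs that differ in a single factor.

factor_columns <- function() {
  c("engine", "qm_size", "functional", "basis", "dielectric", "surroundings",
    "corrections")
}

#' Summarise quality measures by a protocol factor
#'
#' For each level of a configuration factor (QM size, functional, basis,
#' dielectric, surroundings, ...), reports the minimum, mean and maximum of
#' every quality measure over the methods at that level, plus the mean
#' `avg6` and composite rank - the range/average layout of a factor summary
#' table.
#'
#' @param metrics metric tibble from [metric_table()].
#' @param methods method table aligned by `method_id`.
#' @param factor one of the method-table factor columns.
#' @param metric_selection metrics to aggregate; default all twelve columns.
#' @return A long tibble: `factor`, `level`, `n_methods`, `metric`, `min`,
#'   `mean`, `max`. Rows with `metric` `"avg6"` and `"composite_rank"`
#'   summarise the ranking computed over the full panel.
#' @export
summarize_by_factor <- function(metrics, methods, factor,
                                metric_selection = NULL) {
  if (!factor %in% factor_columns()) {
    stop("unknown factor: ", factor, " (expected one of ",
         paste(factor_columns(), collapse = ", "), ")")
  }
  methods <- tibble::as_tibble(methods)
  metrics <- tibble::as_tibble(metrics)
  idx <- match(metrics$method_id, methods$method_id)
  if (anyNA(idx)) {
    stop("method table lacks method_id: ",
         paste(metrics$method_id[is.na(idx)], collapse = ", "))
  }
  if (is.null(metric_selection)) {
    metric_selection <- setdiff(names(metrics), "method_id")
  }
  ranks <- composite_rank(metrics)
  vals <- cbind(metrics[metric_selection],
                ranks[c("avg6", "composite_rank")])
  level <- methods[[factor]][idx]

  rows <- lapply(split(seq_len(nrow(vals)), level), function(i) {
    tibble::tibble(
      factor = factor,
      level = level[i[1L]],
      n_methods = length(i),
      metric = names(vals),
      min = unname(vapply(vals[i, ], min, numeric(1))),
      mean = unname(vapply(vals[i, ], mean, numeric(1))),
      max = unname(vapply(vals[i, ], max, numeric(1)))
    )
  })
  dplyr::bind_rows(rows)
}

#' Matched-pair comparison across one factor
#'
#' Enumerates all pairs of methods that are identical in every
#' configuration field except `factor`, where one sits at `level_a` and the
#' other at `level_b`, and counts which level wins each pair. Wins are
#' decided on the continuous mean six-metric rank (`avg6`, lower is
#' better), with exact equality a tie; the integer composite rank is
#' coarser and would manufacture ties.
#'
#' @param metrics metric tibble from [metric_table()].
#' @param methods method table aligned by `method_id`.
#' @param factor configuration factor to compare.
#' @param level_a,level_b the two levels.
#' @param score `"avg6"` (default) or `"composite_rank"`.
#' @return A one-row tibble: `factor`, `level_a`, `level_b`, `n_pairs`,
#'   `wins_a`, `wins_b`, `ties`. Zero matched pairs yields an empty count
#'   with a warning.
#' @export
paired_comparison <- function(metrics, methods, factor, level_a, level_b,
                              score = c("avg6", "composite_rank")) {
  score <- match.arg(score)
  if (!factor %in% factor_columns()) stop("unknown factor: ", factor)
  methods <- tibble::as_tibble(methods)
  metrics <- tibble::as_tibble(metrics)
  idx <- match(metrics$method_id, methods$method_id)
  if (anyNA(idx)) stop("method table lacks some method_id values")
  methods <- methods[idx, ]

  ranks <- composite_rank(metrics)
  s <- ranks[[score]]

  other <- setdiff(factor_columns(), factor)
  key <- do.call(paste, c(methods[other], sep = "\r"))
  a_rows <- which(methods[[factor]] == level_a)
  b_rows <- which(methods[[factor]] == level_b)

  wins_a <- wins_b <- ties <- 0L
  n_pairs <- 0L
  for (i in a_rows) {
    js <- b_rows[key[b_rows] == key[i]]
    for (j in js) {
      n_pairs <- n_pairs + 1L
      if (s[i] < s[j]) wins_a <- wins_a + 1L
      else if (s[i] > s[j]) wins_b <- wins_b + 1L
      else ties <- ties + 1L
    }
  }
  if (n_pairs == 0L) {
    warning("no matched pairs for ", factor, ": ", level_a, " vs ", level_b)
  }
  tibble::tibble(factor = factor, level_a = level_a, level_b = level_b,
                 n_pairs = n_pairs, wins_a = wins_a, wins_b = wins_b,
                 ties = ties)
}
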