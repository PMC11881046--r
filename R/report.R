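# Orchestration: a serializable run configuration, the end-to-end
# evaluation, calibration-line summaries, and delimited report output.

#' Run configuration for an end-to-end evaluation
#'
#' Captures everything a run needs so that a persisted configuration
#' re-executes to identical outputs: input paths, units, the SHE constant,
#' engine filters, metric selections, the experimental-range mode and the
#' master seed. The configuration is a plain list and serializes to JSON
#' (see [write_evaluation()], which echoes it next to the reports).
#'
#' @param energies,potentials path to an energy table or a potential table
#'   (exactly one; `NULL` for the unused one).
#' @param unit energy unit for `energies` inputs.
#' @param c_she SHE alignment constant, eV.
#' @param include_qmmm include QM/MM methods in rankings (default FALSE:
#'   they are scored but excluded from ranking).
#' @param exp_range `"computed"` (max - min of the reference, the default)
#'   or a number pinning an externally chosen constant such as 0.568.
#' @param metric_selection metrics for the composite rank.
#' @param score_selection metrics for the normalized score
#'   ([composite_metrics()] or `"all"`).
#' @param include_null append the constant-predictor null baseline to the
#'   metric report (never ranked).
#' @param out output directory for [run_evaluation()].
#' @param seed master seed for any stochastic stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(energies = NULL, potentials = NULL,
                       unit = c("eV", "hartree"),
                       c_she = 4.28, include_qmmm = FALSE,
                       exp_range = "computed",
                       metric_selection = composite_metrics(),
                       score_selection = composite_metrics(),
                       include_null = TRUE, out = NULL, seed = 1L) {
  unit <- match.arg(unit)
  if (is.null(energies) == is.null(potentials)) {
    stop("exactly one of `energies` or `potentials` must be given")
  }
  if (!identical(exp_range, "computed") &&
      !(is.numeric(exp_range) && length(exp_range) == 1L)) {
    stop("exp_range must be \"computed\" or a single number")
  }
  structure(list(
    energies = energies, potentials = potentials, unit = unit,
    c_she = c_she, include_qmmm = include_qmmm, exp_range = exp_range,
    metric_selection = metric_selection, score_selection = score_selection,
    include_null = include_null, out = out, seed = as.integer(seed)
  ), class = "run_config")
}

resolve_exp_range <- function(exp_range, reference) {
  if (identical(exp_range, "computed") || is.null(exp_range)) {
    max(reference$e_exp) - min(reference$e_exp)
  } else {
    exp_range
  }
}

#' Evaluate a panel of methods against the experimental reference
#'
#' The full scoring pass: per-method quality measures, per-metric ranks
#' with the six-metric composite rank, and min-max normalized scores.
#' QM/MM methods are excluded from the ranking by default (they are scored,
#' with a message, but continuum-solvated cluster and QM/MM potentials are
#' not ranked against each other); pass `include_qmmm = TRUE` to rank the
#' whole panel.
#'
#' @param table a [potential_table()].
#' @param reference experimental reference (default [bcp_reference()]).
#' @param include_qmmm rank QM/MM rows too?
#' @param exp_range `"computed"` or a number (see [run_config()]).
#' @param metric_selection,score_selection metric sets for the composite
#'   rank and the normalized score.
#' @param include_null append the null baseline row to `$metrics`.
#' @return A list of class `redox_evaluation`: `metrics`, `ranks`,
#'   `scores`, `excluded` (method ids left out of the ranking),
#'   `exp_range`, `reference`.
#' @export
evaluate_methods <- function(table, reference = bcp_reference(),
                             include_qmmm = FALSE,
                             exp_range = "computed",
                             metric_selection = composite_metrics(),
                             score_selection = composite_metrics(),
                             include_null = TRUE) {
  stopifnot(inherits(table, "potential_table"))
  rng <- resolve_exp_range(exp_range, reference)
  metrics <- metric_table(table, reference, exp_range = rng)

  excluded <- character()
  rank_metrics <- metrics
  if (!include_qmmm && "engine" %in% names(table$methods)) {
    is_qmmm <- table$methods$engine == "qm_mm"
    if (any(is_qmmm)) {
      excluded <- table$methods$method_id[is_qmmm]
      message("excluding ", length(excluded),
              " QM/MM method(s) from ranking: ",
              paste(excluded, collapse = ", "))
      rank_metrics <- metrics[!is_qmmm, ]
    }
  }

  ranks <- composite_rank(rank_metrics, metric_selection)
  scores <- normalized_score(rank_metrics, score_selection)

  if (include_null) {
    metrics <- dplyr::bind_rows(
      metrics, null_baseline(reference$e_exp, exp_range = rng)
    )
  }
  structure(list(metrics = metrics, ranks = ranks, scores = scores,
                 excluded = excluded, exp_range = rng, reference = reference),
            class = "redox_evaluation")
}

#' @export
print.redox_evaluation <- function(x, ...) {
  n <- nrow(x$ranks)
  best <- x$ranks$method_id[which.min(x$ranks$composite_rank)]
  cat("<redox_evaluation> ", n, " ranked method(s); composite-rank best: ",
      best, "\n", sep = "")
  cat("  exp_range = ", format(x$exp_range), " V",
      if (length(x$excluded) > 0L)
        paste0("; excluded from ranking: ", length(x$excluded)),
      "\n", sep = "")
  invisible(x)
}

#' Calibration-line summary per method
#'
#' Fits the calibration line (calculated versus experimental) for every
#' method and reports slope, intercept and R-squared, plus per-site
#' residuals before and after subtracting the systematic error (the MSE) -
#' the numbers behind a calculated-versus-experimental scatter with an
#' ideal-agreement line.
#'
#' @param table a [potential_table()].
#' @param reference experimental reference.
#' @return A list with `lines` (tibble: `method_id`, `slope`, `intercept`,
#'   `r2`, `mse`) and `residuals` (long tibble: `method_id`, `site`,
#'   `e_exp`, `e_calc`, `residual`, `residual_trimmed`).
#' @export
calibration_table <- function(table, reference = bcp_reference()) {
  stopifnot(inherits(table, "potential_table"))
  idx <- match(reference$abbr, table$sites)
  if (anyNA(idx)) {
    stop("potential table lacks reference site(s): ",
         paste(reference$abbr[is.na(idx)], collapse = ", "))
  }
  exp <- reference$e_exp
  lines <- lapply(seq_len(nrow(table$values)), function(i) {
    calc <- unname(table$values[i, idx])
    sr <- slope_r2(calc, exp)
    m <- mse(calc, exp)
    tibble::tibble(
      method_id = table$methods$method_id[i],
      slope = sr$slope,
      intercept = mean(calc) - sr$slope * mean(exp),
      r2 = sr$r2,
      mse = m
    )
  })
  resid <- lapply(seq_len(nrow(table$values)), function(i) {
    calc <- unname(table$values[i, idx])
    m <- mse(calc, exp)
    tibble::tibble(
      method_id = table$methods$method_id[i],
      site = reference$abbr, e_exp = exp, e_calc = calc,
      residual = calc - exp,
      residual_trimmed = calc - m - exp
    )
  })
  list(lines = dplyr::bind_rows(lines), residuals = dplyr::bind_rows(resid))
}

#' Write evaluation reports to a directory
#'
#' Emits `metrics.csv` (quality measures per method, null baseline last if
#' present), `ranks.csv` (per-metric ranks, `avg6`, composite rank),
#' `scores.csv` (normalized scores) and, when a configuration is supplied,
#' a `config.json` echo that re-executes to identical outputs. Output is
#' deterministic: running twice produces byte-identical files.
#'
#' @param evaluation a `redox_evaluation` from [evaluate_methods()].
#' @param dir output directory (created if needed).
#' @param config optional [run_config()] to echo.
#' @return `dir`, invisibly.
#' @export
write_evaluation <- function(evaluation, dir, config = NULL) {
  stopifnot(inherits(evaluation, "redox_evaluation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_report_csv <- function(d, file) {
    d <- as.data.frame(d)
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], format_full)
    utils::write.csv(d, file.path(dir, file), row.names = FALSE, quote = FALSE)
  }
  write_report_csv(evaluation$metrics, "metrics.csv")
  write_report_csv(evaluation$ranks, "ranks.csv")
  write_report_csv(evaluation$scores, "scores.csv")
  if (!is.null(config)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      warning("jsonlite not available; skipping config echo")
    } else {
      jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                           auto_unbox = TRUE, null = "null", digits = NA)
    }
  }
  invisible(dir)
}

#' Execute a full evaluation from a run configuration
#'
#' Reads the configured input (energy or potential table), builds the
#' potential table if needed, evaluates, and writes reports to
#' `config$out` when set. A persisted `config.json` re-executes to
#' identical outputs for all deterministic stages.
#'
#' @param config a [run_config()].
#' @param methods optional method table joined to the inputs by
#'   `method_id`.
#' @param reference experimental reference.
#' @return The `redox_evaluation`, invisibly when writing reports.
#' @export
run_evaluation <- function(config, methods = NULL,
                           reference = bcp_reference()) {
  stopifnot(inherits(config, "run_config"))
  model <- potential_model(config$c_she)
  table <- if (!is.null(config$energies)) {
    build_potential_table(read_energy_table(config$energies), model,
                          methods = methods)
  } else {
    read_potential_table(config$potentials, methods = methods)
  }
  ev <- evaluate_methods(
    table, reference = reference, include_qmmm = config$include_qmmm,
    exp_range = config$exp_range,
    metric_selection = config$metric_selection,
    score_selection = config$score_selection,
    include_null = config$include_null
  )
  if (!is.null(config$out)) {
    write_evaluation(ev, config$out, config = config)
    return(invisible(ev))
  }
  ev
}
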