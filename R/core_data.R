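# Reference set, protocol descriptions and delimited-table I/O.

#' Experimental reference set of 12 blue copper protein sites
#'
#' Returns the bundled experimental reference: 12 type-1 Cu sites spanning
#' stellacyanin, plastocyanin, nitrite reductase, cucumber basic protein,
#' rusticyanin (WT, M148Q, M148L), CueO, fungal laccase and azurin
#' (WT, N47D, H35L), with their experimental reduction potentials versus
#' the standard hydrogen electrode.
#'
#' The plastocyanin value is 0.375 V, the average of literature measurements
#' at pH ~7 (reported values range 0.370-0.379 V). Potentials are stored in
#' volts; the underlying measurements are integer millivolt values, so
#' `e_exp * 1000` recovers them exactly.
#'
#' @return A tibble with one row per site and columns `abbr`, `protein`,
#'   `organism`, `pdb`, `mutation` and `e_exp` (volts).
#' @export
#' @examples
#' ref <- bcp_reference()
#' ref[ref$abbr == "Pc", "e_exp"]
#' diff(range(ref$e_exp)) # experimental range in V
bcp_reference <- function() {
  tibble::tibble(
    abbr     = c("Stel", "Pc", "NIR", "CBP", "R-WT", "R-MQ",
                 "R-ML", "CueO", "Lacc", "Az-WT", "Az-ND", "Az-HL"),
    protein  = c("Stellacyanin", "Plastocyanin", "Nitrite reductase",
                 "Cucumber basic protein", "Rusticyanin", "Rusticyanin",
                 "Rusticyanin", "CueO", "Fungal laccase",
                 "Azurin", "Azurin", "Azurin"),
    organism = c("Cucumis sativus", "Populus nigra",
                 "Achromobacter cycloclastes", "Cucumis sativus",
                 "Thiobacillus ferrooxidans", "Thiobacillus ferrooxidans",
                 "Thiobacillus ferrooxidans", "Escherichia coli",
                 "Polyporus versicolor", "Pseudomonas aeruginosa",
                 "Pseudomonas aeruginosa", "Pseudomonas aeruginosa"),
    pdb      = c("1JER", "1PLC", "2BW4", "2CBP", "2CAK", "1E30",
                 "1GY2", "2FQE", "1KYA", "1JZF", "1AZR", "2AZU"),
    mutation = c("WT", "WT", "WT", "WT", "WT", "M148Q",
                 "M148L", "WT", "WT", "WT", "N47D", "H35L"),
    e_exp    = c(265, 375, 240, 306, 667, 563,
                 798, 360, 780, 315, 333, 309) / 1000
  )
}

#' Describe one computational protocol
#'
#' A protocol ("method") is one combination of energy scheme and model
#' choices: QM-cluster in a continuum solvent or subtractive QM/MM, the QM
#' region size, DFT functional, basis set, COSMO dielectric constant, whether
#' the MM surroundings were relaxed during geometry optimisation, and any
#' additive corrections (relativistic X2C, thermostatistical).
#'
#' Constraints enforced: QM/MM protocols carry no dielectric constant
#' (`dielectric = "none"`), and relaxed surroundings are only available for
#' the minimal QM system (larger regions were computed on fixed-surroundings
#' structures only).
#'
#' @param method_id unique label, e.g. `"Int/TPSS/SV(P)/20"`.
#' @param engine `"qm_cluster"` or `"qm_mm"`.
#' @param qm_size `"Min"`, `"Int"` or `"Big"`.
#' @param functional `"TPSS"` or `"B3LYP"`.
#' @param basis `"SV(P)"`, `"TZVPD"` or `"x2c-SVPall"`.
#' @param dielectric `"4"`, `"20"`, `"80"` or `"none"`.
#' @param surroundings `"fixed"` or `"relaxed"`.
#' @param corrections character vector, subset of `c("x2c", "thermo")`;
#'   stored as a `+`-joined string so method tables stay flat.
#' @return A one-row tibble (a method table row).
#' @seealso [validate_methods()]
#' @export
method_config <- function(method_id, engine = "qm_cluster", qm_size = "Int",
                          functional = "TPSS", basis = "SV(P)",
                          dielectric = "20", surroundings = "fixed",
                          corrections = character()) {
  m <- tibble::tibble(
    method_id = as.character(method_id),
    engine = engine, qm_size = qm_size, functional = functional,
    basis = basis, dielectric = as.character(dielectric),
    surroundings = surroundings,
    corrections = paste(sort(corrections), collapse = "+")
  )
  validate_methods(m)
}

#' Validate a method table
#'
#' Checks one row per protocol against the allowed factor levels and the
#' structural constraints (QM/MM implies no dielectric; relaxed surroundings
#' only with the Min QM system; unique `method_id`).
#'
#' @param methods a tibble/data.frame with the columns produced by
#'   [method_config()].
#' @return The validated table, invisibly coerced to a tibble.
#' @export
validate_methods <- function(methods) {
  methods <- tibble::as_tibble(methods)
  req <- c("method_id", "engine", "qm_size", "functional", "basis",
           "dielectric", "surroundings", "corrections")
  missing_cols <- setdiff(req, names(methods))
  if (length(missing_cols) > 0L) {
    stop("method table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(methods$method_id)) {
    stop("duplicated method_id: ",
         paste(unique(methods$method_id[duplicated(methods$method_id)]), collapse = ", "))
  }
  chk <- function(col, levels) {
    bad <- setdiff(unique(methods[[col]]), levels)
    if (length(bad) > 0L) {
      stop("invalid ", col, " value(s): ", paste(bad, collapse = ", "))
    }
  }
  chk("engine", c("qm_cluster", "qm_mm"))
  chk("qm_size", c("Min", "Int", "Big"))
  chk("functional", c("TPSS", "B3LYP"))
  chk("basis", c("SV(P)", "TZVPD", "x2c-SVPall"))
  chk("dielectric", c("4", "20", "80", "none"))
  chk("surroundings", c("fixed", "relaxed"))
  corr_parts <- setdiff(unlist(strsplit(methods$corrections, "+", fixed = TRUE)), "")
  bad <- setdiff(corr_parts, c("x2c", "thermo"))
  if (length(bad) > 0L) stop("invalid corrections: ", paste(bad, collapse = ", "))
  bad <- methods$engine == "qm_mm" & methods$dielectric != "none"
  if (any(bad)) {
    stop("QM/MM methods must have dielectric = \"none\": ",
         paste(methods$method_id[bad], collapse = ", "))
  }
  bad <- methods$surroundings == "relaxed" & methods$qm_size != "Min"
  if (any(bad)) {
    stop("relaxed surroundings only allowed with qm_size = \"Min\": ",
         paste(methods$method_id[bad], collapse = ", "))
  }
  methods
}

# ---- energy records -------------------------------------------------------

#' Assemble per-state energy records
#'
#' One record per (method, site, state) with the raw electronic (or QM/MM
#' total) energy and an optional additive correction in the same unit.
#' A valid set carries exactly one record per key and a single unit
#' throughout.
#'
#' @param method_id,site,state,energy vectors of equal length; `state` is
#'   `"oxidized"` or `"reduced"`.
#' @param correction additive per-state term (default 0), same unit.
#' @param unit `"hartree"` or `"eV"`, applied to the whole set.
#' @return A tibble with columns `method_id`, `site`, `state`, `energy`,
#'   `correction`, `unit`.
#' @export
energy_records <- function(method_id, site, state, energy, correction = 0,
                           unit = c("eV", "hartree")) {
  unit <- match.arg(unit)
  rec <- tibble::tibble(
    method_id = as.character(method_id), site = as.character(site),
    state = state, energy = as.numeric(energy),
    correction = as.numeric(correction), unit = unit
  )
  validate_energy_records(rec)
}

validate_energy_records <- function(rec) {
  rec <- tibble::as_tibble(rec)
  req <- c("method_id", "site", "state", "energy", "correction", "unit")
  missing_cols <- setdiff(req, names(rec))
  if (length(missing_cols) > 0L) {
    stop("energy table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- setdiff(unique(rec$state), c("oxidized", "reduced"))
  if (length(bad) > 0L) stop("invalid state value(s): ", paste(bad, collapse = ", "))
  if (length(unique(rec$unit)) > 1L) {
    stop("mixed units in one energy set: ", paste(unique(rec$unit), collapse = ", "))
  }
  bad <- setdiff(unique(rec$unit), c("hartree", "eV"))
  if (length(bad) > 0L) stop("invalid unit: ", paste(bad, collapse = ", "))
  if (!all(is.finite(rec$energy)) || !all(is.finite(rec$correction))) {
    stop("non-finite energy or correction")
  }
  key <- paste(rec$method_id, rec$site, rec$state, sep = "\r")
  if (anyDuplicated(key)) {
    d <- rec[duplicated(key), c("method_id", "site", "state")]
    stop("duplicate (method, site, state) record(s): ",
         paste(paste(d$method_id, d$site, d$state, sep = "/"), collapse = ", "))
  }
  rec
}

#' Read / write a per-state energy table
#'
#' Plain CSV with columns `method_id, site, state, energy, correction, unit`.
#' The unit column must be constant (`hartree` or `eV`); duplicated
#' (method, site, state) keys are rejected.
#'
#' @param path file path.
#' @return `read_energy_table()` returns a validated record tibble;
#'   `write_energy_table()` returns `path` invisibly.
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e))
  )
  if (!"correction" %in% names(raw)) raw$correction <- 0
  for (col in c("energy", "correction")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0L) {
      stop("parse error in ", path, ": non-numeric ", col,
           " at data line ", bad[1L])
    }
    raw[[col]] <- v
  }
  validate_energy_records(raw)
}

#' @rdname read_energy_table
#' @param records a validated energy record tibble.
#' @export
write_energy_table <- function(records, path) {
  records <- validate_energy_records(records)
  out <- as.data.frame(records)
  out$energy <- format_full(out$energy)
  out$correction <- format_full(out$correction)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Full-precision decimal rendering so write/read round-trips are exact.
format_full <- function(x) formatC(x, format = "g", digits = 17)

# ---- potential tables -----------------------------------------------------

#' Construct a method-by-site potential table
#'
#' The central container: a complete matrix of computed reduction potentials
#' (volts), one row per method, one column per site. An optional method
#' table (see [method_config()]) rides along for ranking and factor
#' analysis.
#'
#' @param values numeric matrix, methods x sites, all finite.
#' @param methods optional method table; row order must match `values`. A
#'   character vector is accepted as bare method ids.
#' @param sites site abbreviations; defaults to `colnames(values)`.
#' @return An object of class `potential_table`.
#' @export
potential_table <- function(values, methods = NULL, sites = colnames(values)) {
  values <- as.matrix(values)
  if (length(values) == 0L) stop("empty potential table")
  if (is.null(sites)) stop("sites must be named (colnames or `sites`)")
  if (length(sites) != ncol(values)) stop("length(sites) != ncol(values)")
  if (is.character(methods)) methods <- tibble::tibble(method_id = methods)
  if (is.null(methods)) {
    ids <- rownames(values)
    if (is.null(ids)) ids <- paste0("method", seq_len(nrow(values)))
    methods <- tibble::tibble(method_id = ids)
  }
  methods <- tibble::as_tibble(methods)
  if (nrow(methods) != nrow(values)) stop("nrow(methods) != nrow(values)")
  if (anyDuplicated(methods$method_id)) stop("duplicated method_id")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite potential at method ", methods$method_id[bad[1L]],
         ", site ", sites[bad[2L]])
  }
  dimnames(values) <- list(methods$method_id, sites)
  structure(list(values = values, methods = methods, sites = as.character(sites)),
            class = "potential_table")
}

#' @export
print.potential_table <- function(x, ...) {
  cat("<potential_table> ", nrow(x$values), " method(s) x ",
      ncol(x$values), " site(s), E° in V\n", sep = "")
  print(round(x$values, 3))
  invisible(x)
}

#' @export
dim.potential_table <- function(x) dim(x$values)

#' Read / write a potential table
#'
#' CSV layout: one `method_id` column followed by one column per site, cells
#' in volts. Round-trips are value-exact (full decimal precision on write).
#'
#' @param path file path.
#' @param methods optional method table joined onto the read matrix by
#'   `method_id`.
#' @return `read_potential_table()` returns a [potential_table()];
#'   `write_potential_table()` returns `path` invisibly.
#' @export
read_potential_table <- function(path, methods = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty potential table: ", path)
  if (names(raw)[1L] != "method_id") {
    stop("parse error in ", path, ": first column must be method_id")
  }
  ids <- as.character(raw[[1L]])
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  if (is.character(vals)) {
    num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (length(bad) > 0L) {
      stop("parse error in ", path, ": non-numeric cell at row ", bad[1L, 1L],
           ", site column ", colnames(raw)[-1L][bad[1L, 2L]])
    }
    vals <- num
  }
  if (is.null(methods)) methods <- tibble::tibble(method_id = ids)
  else {
    methods <- tibble::as_tibble(methods)
    idx <- match(ids, methods$method_id)
    if (anyNA(idx)) stop("methods table lacks method_id: ",
                         paste(ids[is.na(idx)], collapse = ", "))
    methods <- methods[idx, ]
  }
  potential_table(vals, methods = methods, sites = names(raw)[-1L])
}

#' @rdname read_potential_table
#' @param table a [potential_table()].
#' @export
write_potential_table <- function(table, path) {
  stopifnot(inherits(table, "potential_table"))
  out <- data.frame(method_id = table$methods$method_id,
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_along(table$sites)) {
    out[[table$sites[j]]] <- format_full(table$values[, j])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
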