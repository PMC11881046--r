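# Synthetic benchmark generator: shift/slope/noise error model per method,
# a study-like factor grid, and energy records that round-trip through the
# potential pipeline. All randomness flows from one master seed; each
# method gets an independent stream derived from its method_id.

# Stable 31-bit hash of a string, combined with the master seed, so each
# method's draw is reproducible and independent of panel order.
method_seed <- function(master_seed, method_id) {
  bytes <- utf8ToInt(method_id)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer((h + as.numeric(master_seed) * 2654435761) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate one method's potentials under a shift/slope/noise error model
#'
#' `calc_i = shift + slope * exp_i + eps_i`, with `eps_i` i.i.d. Gaussian
#' with standard deviation `sigma` (volts). This is the error structure the
#' evaluation suite assumes: a systematic offset, a distortion of the
#' potential scale, and site-level scatter.
#'
#' @param exp experimental potentials, V.
#' @param shift systematic offset `a`, V.
#' @param slope scale distortion `b` (1 = faithful).
#' @param sigma noise standard deviation, V (>= 0).
#' @param seed integer; fixed seed gives bitwise-reproducible output.
#' @return Simulated calculated potentials, same length as `exp`.
#' @export
generate_method_potentials <- function(exp, shift = 0, slope = 1, sigma = 0,
                                       seed = 1L) {
  stopifnot(length(exp) >= 1L, all(is.finite(exp)), sigma >= 0)
  eps <- if (sigma > 0) with_seed(seed, stats::rnorm(length(exp), 0, sigma))
         else rep(0, length(exp))
  shift + slope * exp + eps
}

#' Factor grid and error-model effects for a synthetic benchmark
#'
#' Describes a full factorial design over QM-cluster protocol factors
#' together with the error-model parameters of each cell: per-level
#' additive effects on the systematic shift `a`, multiplicative effects on
#' the slope `b`, and a per-size noise level `sigma`.
#'
#' The defaults emulate the study-scale QM-cluster panel: 48 methods
#' (Min with fixed/relaxed surroundings x 2 functionals x 2 basis sets x
#' 3 dielectrics = 24, plus Int and Big fixed-surroundings grids of 12
#' each), with shifts spanning about -1.2 to -0.3 V and slopes about
#' 0.5-2: the Min region compresses the potential scale, the Big region
#' stretches it, higher dielectric constants scale potentials down, and
#' the intermediate region with a moderate dielectric sits closest to
#' slope 1.
#'
#' @param shift_base,slope_base baseline shift (V) and slope.
#' @param shift_effects named list of named numeric vectors: additive shift
#'   effect per factor level.
#' @param slope_effects named list of named numeric vectors: multiplicative
#'   slope effect per factor level.
#' @param sigma_by_size named vector: noise sd (V) per QM size.
#' @param sigma_relaxed_extra extra noise sd (V) for relaxed surroundings.
#' @return An object of class `synthetic_design`: the method table plus
#'   per-method true `shift`, `slope`, `sigma`.
#' @export
synthetic_design <- function(shift_base = -0.9,
                             slope_base = 1,
                             shift_effects = list(
                               qm_size = c(Min = -0.05, Int = -0.2, Big = 0.35),
                               functional = c(TPSS = 0, B3LYP = 0.1),
                               basis = c(`SV(P)` = 0, TZVPD = 0.1),
                               dielectric = c(`4` = -0.1, `20` = 0, `80` = 0.05)
                             ),
                             slope_effects = list(
                               qm_size = c(Min = 0.65, Int = 0.9, Big = 1.65),
                               functional = c(TPSS = 1, B3LYP = 1.05),
                               basis = c(`SV(P)` = 1, TZVPD = 0.95),
                               dielectric = c(`4` = 1.15, `20` = 1, `80` = 0.85)
                             ),
                             sigma_by_size = c(Min = 0.06, Int = 0.04, Big = 0.05),
                             sigma_relaxed_extra = 0.01) {
  grid_min <- expand.grid(
    qm_size = "Min", functional = c("TPSS", "B3LYP"),
    basis = c("SV(P)", "TZVPD"), dielectric = c("4", "20", "80"),
    surroundings = c("fixed", "relaxed"),
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  grid_ib <- expand.grid(
    qm_size = c("Int", "Big"), functional = c("TPSS", "B3LYP"),
    basis = c("SV(P)", "TZVPD"), dielectric = c("4", "20", "80"),
    surroundings = "fixed",
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  grid <- rbind(grid_min, grid_ib)

  methods <- tibble::tibble(
    method_id = paste(grid$qm_size, grid$functional, grid$basis,
                      grid$dielectric,
                      ifelse(grid$surroundings == "relaxed", "relaxed", "fixed"),
                      sep = "/"),
    engine = "qm_cluster",
    qm_size = grid$qm_size, functional = grid$functional, basis = grid$basis,
    dielectric = grid$dielectric, surroundings = grid$surroundings,
    corrections = ""
  )
  methods <- validate_methods(methods)

  eff <- function(effects, col) {
    vapply(methods[[col]], function(lv) effects[[col]][[lv]], numeric(1))
  }
  shift <- shift_base +
    eff(shift_effects, "qm_size") + eff(shift_effects, "functional") +
    eff(shift_effects, "basis") + eff(shift_effects, "dielectric")
  slope <- slope_base *
    eff(slope_effects, "qm_size") * eff(slope_effects, "functional") *
    eff(slope_effects, "basis") * eff(slope_effects, "dielectric")
  sigma <- unname(sigma_by_size[methods$qm_size]) +
    ifelse(methods$surroundings == "relaxed", sigma_relaxed_extra, 0)

  structure(
    list(methods = methods,
         truth = tibble::tibble(method_id = methods$method_id,
                                shift = unname(shift), slope = unname(slope),
                                sigma = unname(sigma))),
    class = "synthetic_design"
  )
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat("<synthetic_design> ", nrow(x$methods), " methods; shift [",
      round(min(x$truth$shift), 2), ", ", round(max(x$truth$shift), 2),
      "] V, slope [", round(min(x$truth$slope), 2), ", ",
      round(max(x$truth$slope), 2), "]\n", sep = "")
  invisible(x)
}

#' Generate a synthetic benchmark table with known ground truth
#'
#' Draws every method's potentials from its error-model cell and returns
#' the complete method-by-site table together with the true parameters, so
#' ranking behaviour and parameter recovery can be tested end to end.
#'
#' @param design a [synthetic_design()].
#' @param exp experimental potentials; defaults to the bundled reference.
#' @param seed master seed; per-method streams are derived from it and the
#'   method_id, so output is independent of method order.
#' @param sites site labels; defaults to the bundled reference abbreviations.
#' @return A list with `table` (a [potential_table()]) and `truth` (tibble
#'   of per-method `shift`, `slope`, `sigma`).
#' @export
generate_benchmark <- function(design = synthetic_design(),
                               exp = bcp_reference()$e_exp,
                               seed = 1L,
                               sites = bcp_reference()$abbr) {
  stopifnot(inherits(design, "synthetic_design"))
  if (length(sites) != length(exp)) stop("sites and exp lengths differ")
  n <- nrow(design$methods)
  vals <- matrix(NA_real_, nrow = n, ncol = length(exp))
  for (i in seq_len(n)) {
    tr <- design$truth[i, ]
    vals[i, ] <- generate_method_potentials(
      exp, shift = tr$shift, slope = tr$slope, sigma = tr$sigma,
      seed = method_seed(seed, tr$method_id)
    )
  }
  list(table = potential_table(vals, methods = design$methods, sites = sites),
       truth = design$truth)
}

#' Expand a potential table into per-state energy records
#'
#' Emits one oxidized/reduced record pair per table entry such that
#' `e_ox - e_red = E0 + c_she`; rebuilding the table with
#' [build_potential_table()] recovers the input to machine precision. The
#' reduced-state energies sit at `base_energy` plus a seeded uniform
#' offset, giving each pair a distinct absolute scale as real calculations
#' would.
#'
#' @param table a [potential_table()].
#' @param model a [potential_model()] fixing `c_she`.
#' @param base_energy reduced-state energy level, eV.
#' @param seed integer seed for the per-pair offsets.
#' @return An energy record tibble in eV.
#' @export
generate_energy_records <- function(table, model = potential_model(),
                                    base_energy = -8000, seed = 1L) {
  stopifnot(inherits(table, "potential_table"))
  ids <- table$methods$method_id
  grid <- expand.grid(site = table$sites, method_id = ids,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  e_red <- base_energy +
    with_seed(seed, stats::runif(nrow(grid), -1, 1))
  e0 <- as.vector(t(table$values)) # row-major: site fastest, matching grid
  e_ox <- e_red + e0 + model$c_she
  energy_records(
    method_id = rep(grid$method_id, 2L),
    site = rep(grid$site, 2L),
    state = rep(c("oxidized", "reduced"), each = nrow(grid)),
    energy = c(e_ox, e_red),
    unit = "eV"
  )
}
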