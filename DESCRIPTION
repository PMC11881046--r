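Package: redoxbench
Title: Benchmarking Computed Redox Potentials of Blue Copper Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation framework for benchmarking computed reduction
    potentials of blue copper protein (type-1 Cu) sites against experiment.
    Converts oxidized/reduced state energies (QM-cluster or subtractive
    QM/MM) to potentials on the standard hydrogen electrode scale, scores
    each computational protocol with a ten-metric quality suite (signed and
    absolute errors, systematic-error-trimmed deviations, range, calibration
    slope with a symmetric penalty transform, R-squared, Spearman's rho and
    Kendall's tau), combines the metrics into a six-metric composite rank
    and a min-max normalized score, compares against a constant-predictor
    null baseline, and aggregates performance across protocol factors
    (QM system size, functional, basis set, dielectric constant,
    surroundings treatment). Includes a synthetic benchmark generator with
    a shift/slope/noise error model for end-to-end testing and parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
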