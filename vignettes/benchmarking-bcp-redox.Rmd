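---
title: "Benchmarking computed redox potentials of blue copper proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking computed redox potentials of blue copper proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxbench)
```

## The problem

Blue copper proteins (BCPs) carry a mononuclear type-1 Cu site — a
Cys/His/His trigonal plane, usually with an axial Met or Gln — that shuttles
one electron between the Cu(II) and Cu(I) states. Their reduction potentials
E° span roughly 0.2–0.8 V versus the standard hydrogen electrode (SHE), and
computing them accurately is hard: quantum-chemical protocols differ in the
size of the quantum region, the density functional, the basis set, whether
the protein is represented by a dielectric continuum (QM-cluster) or an
explicit classical environment (QM/MM), and whether the surroundings are
relaxed. `redoxbench` is the scoring side of that problem: given a panel of
protocols and their computed potentials for a common set of sites, it
quantifies how well each protocol reproduces experiment and how the
protocol factors drive the differences.

The bundled reference set (`bcp_reference()`) contains twelve
experimentally characterized sites — stellacyanin, plastocyanin, nitrite
reductase, cucumber basic protein, rusticyanin (WT, M148Q, M148L), CueO,
fungal laccase, and azurin (WT, N47D, H35L) — with potentials stored in
volts. The plastocyanin entry is 0.375 V, the average of literature values
that range 0.370–0.379 V.

## From state energies to potentials

For a one-electron reduction, the potential follows from the energies of
the two redox states:

$$E^\circ = \big(E_\text{ox} - E_\text{red}\big) - c$$

with all energies in eV so the difference maps one-to-one to volts.
`compute_potential()` implements this with the SHE alignment constant
`c_she` defaulting to 4.28 eV; proposed values span about 4.05–4.44 eV, and
`potential_model()` warns (but does not fail) outside that band. Because a
change in `c` shifts every potential by the same amount, it cannot affect
any shift-invariant quality measure — a property the test suite checks
directly. The one-electron assumption is hardcoded: every site in scope is
a type-1 Cu centre.

QM/MM total energies, when they are assembled here rather than upstream,
use the subtractive electrostatic-embedding form
(`combine_qmmm_energy()`): the QM energy of the active region polarized by
the surrounding point charges, minus the classical energy of the truncated
region with its charges zeroed, plus the classical energy of the full
system with the QM-region charges zeroed.

Additive per-state corrections (relativistic X2C shifts, thermostatistical
terms from frequency calculations) are consumed as plain numbers attached
to each energy record and applied before conversion
(`apply_corrections()`). Whether such corrections are best applied to free
energies or electronic energies is a modelling question outside this
package; treating them as per-state additive terms is the interface
decision, and it preserves linearity: an ox-state correction of +0.05 eV
raises that potential by exactly 0.05 V.

Hartree inputs are converted with the CODATA factor 27.211386 eV/Eh,
declared in exactly one place.

## The quality suite

Ten measures compare one method's potentials `calc` with experiment `exp`
(all in volts; sign convention calculated − experimental):

* **MSE** — mean signed error; the systematic, absolute-scale error.
* **MAD**, **MAX** — mean and maximum absolute deviation.
* **MADtr**, **MAXtr** — the same after subtracting the MSE from all
  predictions; shift-invariant measures of *relative* accuracy.
* **range** — spread of the calculated potentials, and **Rel Range**, the
  absolute deviation of that spread from the experimental range.
* **slope** — ordinary least-squares slope of `calc` on `exp` (experiment
  on the x-axis, as in a calibration plot), and **Rel Slope**, the
  symmetric penalty `1 − 1/k` for `k ≥ 1`, `1 − k` for `0 < k < 1`, so
  doubling and halving the scale are penalized equally
  (`rel_slope(k) == rel_slope(1/k)`). Non-positive slopes map to 1, the
  worst value; an anti-correlated predictor should never outscore a merely
  flat one.
* **R²** — the squared Pearson correlation. It is treated as a correlation
  measure (alongside ρ and τ), not the coefficient of determination of a
  fitted model, and is defined as 0 for a constant predictor.
* **ρ**, **τ** — Spearman and Kendall rank correlations; τ is the τ-b
  statistic over all n(n−1)/2 site pairs (66 pairs for 12 sites), with the
  standard tie correction. The experimental values are distinct, so ties
  only arise in degenerate synthetic input.

The experimental range used by Rel Range defaults to the value computed
from the loaded reference (0.558 V for the bundled set). Published
discussions of this data set have also used 0.568 V for the same quantity;
since the two differ, the package never silently prefers one — the default
is the computed value, and `exp_range = 0.568` (or any number) pins the
alternative explicitly.

## Composite rank and normalized score

Single metrics disagree systematically: R², ρ and τ reward methods that
spread the potentials widely, while MADtr and MAXtr reward conservative,
narrow predictions. Two aggregation schemes are provided.

**Composite rank** (`composite_rank()`): each method is ranked on six
metrics — MADtr, MAXtr, R², τ, Rel Range, Rel Slope — and the composite is
the rank of the mean rank (`avg6`). ρ is excluded for its near-perfect
correlation with τ; the selection balances two small-range-favouring
metrics, two large-range-favouring ones, and two magnitude anchors. Ties
receive average (fractional) ranks, a deterministic convention that
preserves each column's rank sum at M(M+1)/2. Ranks compare values at 12
significant digits, so quantities equal up to double-precision rounding
noise (two exact-fit R² values of 1) tie instead of being ordered by
floating-point jitter.

**Normalized score** (`normalized_score()`): each metric is min–max
rescaled over the panel so 0 is the best observed value and 1 the worst,
and the total is the mean. Ranks see only order, so the composite rank is
invariant to any strictly monotone rescaling of a metric; the normalized
score is invariant only to affine rescaling. That difference is the
mechanism by which the two schemes can crown different methods: min–max
scaling de-emphasizes metrics with wide observed spreads (range, slope)
and up-weights narrow ones (R², τ), favouring large-QM-system protocols.
Both behaviours are property-tested. The score defaults to the same six
metrics as the composite rank; `metric_selection = "all"` uses all ten
measures, with range and slope entering through their deviation transforms
(Rel Range, Rel Slope) and MSE by absolute value so that 0 remains optimal
in every column.

**Null baseline** (`null_baseline()`): predicting the same value for every
site is the floor of predictive power. Its MADtr reduces to the mean
absolute deviation of the experimental values about their mean — 0.17 V
for the bundled reference, with MAXtr 0.36 V — and R², ρ, τ, slope and
range are all 0 by convention (the correlations are undefined for a
constant predictor). Its MSE depends on the arbitrary constant chosen; the
default constant is `mean(exp)`, which zeroes it, and the trimmed metrics
are unaffected by that choice. The baseline is appended to metric reports
but never ranked.

By default QM/MM methods are scored but excluded from rankings
(`include_qmmm = FALSE`): continuum-solvated cluster calculations and
QM/MM potentials, whose calculated ranges can differ by an order of
magnitude, are not meaningfully ranked against each other.

## Factor analysis

`summarize_by_factor()` aggregates each quality measure over all methods
sharing a factor level (min/mean/max per level, plus mean `avg6` and
composite rank), mirroring a range-and-average summary table.
`paired_comparison()` isolates one factor: it enumerates every pair of
methods identical in all other configuration fields (corrections
included), and counts wins by the continuous `avg6` score, with exact
equality a tie. `avg6` rather than the integer composite rank avoids
manufacturing ties from rank coarsening; the integer-rank variant is
available via `score = "composite_rank"`. In a study-shaped panel
(24 Min + 12 Int + 12 Big QM-cluster methods), pairing on functional or on
basis set yields exactly 24 matched pairs.

## The synthetic benchmark

`synthetic_design()` and `generate_benchmark()` produce panels with known
ground truth so every pipeline stage is testable without external data.
Each method's potentials follow a three-parameter error model

$$\text{calc}_i = a + b\,\text{exp}_i + \varepsilon_i,
  \qquad \varepsilon_i \sim \mathcal{N}(0, \sigma^2)$$

— a systematic shift `a` (V), a scale distortion `b`, and homoscedastic
Gaussian site noise `σ` (V). Gaussian homoscedastic noise is the simplest
defensible choice; no empirical error distribution is assumed. The default
design is a 48-method QM-cluster grid shaped like the study panel (Min
with fixed/relaxed surroundings × 2 functionals × 2 basis sets × 3
dielectrics = 24, plus fixed-surroundings Int and Big grids of 12 each),
with per-factor effects chosen once to land in the reported error regime:
shifts span −1.2 to −0.3 V (systematic underestimation, strongest for
intermediate regions with low dielectric), slopes span ≈0.52–1.99 (the Min
region compresses the potential scale, the Big region overstretches it,
higher dielectric constants scale potentials down), and σ is 0.04–0.07 V.
`generate_energy_records()` expands any potential table into
oxidized/reduced state-energy pairs that round-trip through
`build_potential_table()` to machine precision.

What the generator emulates is the *error structure* of a method panel —
offset, scale distortion, scatter, factor-driven trends. What it does not
emulate: correlated errors between methods sharing a functional or
geometry, site-specific systematic failures (e.g. a particular mutant
mis-modelled by all small-region methods), or heteroscedastic noise. Tests
passing on synthetic data therefore validate the scoring machinery and its
invariants, not the chemistry of any real protocol.

Randomness is reproducible and order-independent: each method's noise
stream is seeded by a stable hash of its `method_id` combined with the
master seed, so subsetting or reordering a panel never changes a method's
simulated potentials.

## Numerical choices and degenerate inputs

* Slope/R² require ≥ 3 paired values and a non-constant experimental set;
  a constant `calc` yields slope 0 and R² 0 rather than an error.
* `null_baseline()` is built directly from the error metrics, so it works
  even on a degenerate (all-equal) experimental set.
* Ranking ties: average ranks, at 12-significant-digit comparison
  precision (see above).
* Missing matrix entries are rejected at table construction; incomplete
  oxidized/reduced pairs fail with the offending (method, site) named.
* File round-trips write numbers at 17 significant digits, so
  write-then-read is value-exact.

## Problem sizes

The test suite and acceptance script run the full pipeline at the study's
natural scale — 48–64 methods × 12 sites — plus a 1000-replicate slope
recovery study at σ = 0.1 V, all of which completes in seconds. Larger
panels are unnecessary: every operation is O(methods × sites) or
O(methods²) at worst (pair matching), and the statistical tests are
calibrated to their replicate counts via standard errors, not fixed
tolerances.

## Limitations

* All quantum-chemical content (functionals, solvation models,
  geometries, X2C, frequencies) is upstream; this package scores numbers.
* No uncertainty quantification on the metrics (no bootstrap or
  significance tests on rank differences) — point values only, as the
  benchmarking workflow it supports reports them.
* The composite-rank metric selection and the normalized score's default
  selection are conventions, configurable but not data-driven.
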