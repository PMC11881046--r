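# redoxbench

Benchmarking computed redox potentials of blue copper proteins.

Blue copper proteins (BCPs) carry a type-1 Cu site that transfers one
electron between Cu(II) and Cu(I); their reduction potentials E° span about
0.2–0.8 V vs the standard hydrogen electrode (SHE). Quantum-chemical
protocols for computing E° differ in QM region size (Min/Int/Big),
functional (TPSS/B3LYP), basis set, continuum dielectric constant
(ε = 4/20/80), environment treatment (QM-cluster vs QM/MM) and
surroundings relaxation — and no single error statistic orders them
fairly. `redoxbench` is for computational chemists running such method
panels: it converts per-state energies to potentials, scores every
protocol with a ten-metric quality suite, aggregates the metrics into two
composite scoring schemes, and dissects performance by protocol factor.

## The model

For a one-electron reduction, with state energies in eV,

    E° = (E_ox − E_red) − c,        c = 4.28 eV (SHE alignment)

QM/MM total energies use the subtractive electrostatic-embedding
assembly `E = E_QM1+ptch23 − E_MM1,q=0 + E_MM123,q=0`.

Each method's potentials `calc` are compared with experiment `exp` by:
MSE, MAD, MAX; MADtr and MAXtr (MAD/MAX after subtracting the MSE —
relative-potential accuracy); the range of `calc` and **Rel Range**
`|range(calc) − range(exp)|`; the calibration slope k (OLS of calc on exp)
and **Rel Slope** (`1 − 1/k` for k ≥ 1, `1 − k` for 0 < k < 1, a symmetric
penalty with `rel_slope(k) = rel_slope(1/k)`); R² (squared Pearson);
Spearman's ρ and Kendall's τ (τ-b over all 66 site pairs for 12 sites).

Two aggregations: the **composite rank** — rank of the mean per-metric
rank over MADtr, MAXtr, R², τ, Rel Range, Rel Slope — and the **min–max
normalized score**, where each metric is rescaled to [0, 1] over the panel
(0 = best observed) and averaged. A constant-predictor **null baseline**
(MADtr 0.17 V, MAXtr 0.36 V on the bundled reference; R² = ρ = τ = slope
= range = 0) marks the floor of predictive power.

The package ships the 12-site experimental reference (stellacyanin,
plastocyanin, nitrite reductase, cucumber basic protein, rusticyanin
WT/M148Q/M148L, CueO, fungal laccase, azurin WT/N47D/H35L) and a
synthetic benchmark generator (`calc = a + b·exp + ε`) with a
study-shaped 48-method factor grid and known ground truth.

## Worked example

```r
library(redoxbench)

ref <- bcp_reference()
head(ref[, c("abbr", "pdb", "mutation", "e_exp")], 4)
#>   abbr  pdb   mutation e_exp
#> 1 Stel  1JER  WT       0.265
#> 2 Pc    1PLC  WT       0.375
#> 3 NIR   2BW4  WT       0.24
#> 4 CBP   2CBP  WT       0.306

# a study-shaped synthetic panel: 48 QM-cluster methods x 12 sites
bench <- generate_benchmark(synthetic_design(), seed = 42)
ev <- evaluate_methods(bench$table)
ev
#> <redox_evaluation> 48 ranked method(s); composite-rank best: Int/B3LYP/SV(P)/4/fixed
#>   exp_range = 0.558 V

top <- merge(ev$ranks[, c("method_id", "avg6", "composite_rank")],
             ev$metrics[, c("method_id", "mse", "madtr", "maxtr", "r2", "tau")])
top[order(top$composite_rank), ][1:3, ]
#>   method_id                 avg6 composite_rank    mse  madtr  maxtr    r2   tau
#> 1 Int/B3LYP/SV(P)/4/fixed   5.75              1 -1.06  0.0225 0.0598 0.985 0.788
#> 2 Int/B3LYP/SV(P)/20/fixed  6.58              2 -1.03  0.0333 0.0845 0.960 0.939
#> 3 Int/B3LYP/TZVPD/4/fixed   6.75              3 -0.976 0.0310 0.0706 0.969 0.909
```

Reading the top row: the best-ranked cell underestimates every potential
by about 1.06 V (MSE) but reproduces the *relative* potentials to 0.02 V
on average (MADtr) with strong rank agreement (τ = 0.79) — the typical
profile of a well-calibrated intermediate-size QM-cluster protocol. The
null baseline puts those numbers in context:

```r
null_baseline(ref$e_exp)[, c("madtr", "maxtr", "r2", "rho", "tau")]
#>   madtr maxtr    r2   rho   tau
#> 1 0.173 0.355     0     0     0
```

Factor-wise, a matched-pair comparison isolates one design choice:

```r
paired_comparison(ev$metrics[ev$metrics$method_id != "null", ],
                  bench$table$methods, "functional", "B3LYP", "TPSS")
#>   factor     level_a level_b n_pairs wins_a wins_b  ties
#> 1 functional B3LYP   TPSS         24     16      8     0
```

i.e. among the 24 pairs of methods identical except for the functional,
B3LYP wins 16 under this seed's error realization.

Real panels enter the same way, then flow through `evaluate_methods()`,
`summarize_by_factor()`, `calibration_table()` and `write_evaluation()`.
Two CSV schemas are read and written:

* **potential table** (`read_potential_table()`): one `method_id` column,
  then one column per site (headers = site abbreviations), cells = E° in
  volts. Complete matrix required.
* **energy table** (`read_energy_table()`): columns
  `method_id, site, state, energy, correction, unit` with
  `state ∈ {oxidized, reduced}` and a constant `unit ∈ {hartree, eV}`;
  exactly one row per (method, site, state), `correction` an additive
  per-state term (default 0).

Method metadata (engine, QM size, functional, basis, dielectric,
surroundings, corrections) is a flat table built with `method_config()` /
`validate_methods()` and joined by `method_id`.

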