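# levyrisk

Why do lifetime cancer risks differ by orders of magnitude between
tissues? `levyrisk` implements a one-dimensional, parameter-free model of
carcinogenesis for exploring that question: the expression state of a
small portion of tissue (a *microstate*) is a point in gene expression
space, normal and tumor samples form two separated clouds along the first
principal component (PC1), and tumorigenesis is the first passage of a
random walk from the normal cloud across the gap of width
`R = x̄₁ − Rₙ − Rₜ` to the tumor cloud. Per stem-cell generation the walk
takes a bounded step of scale `D` (the largest PC1 gene loading) and,
rarely, a large Pareto-tailed "Lévy" jump. The package is aimed at
quantitative cancer biologists and biostatisticians who want to fit,
score or stress-test this class of risk model.

Two closed-form predictors for `ln(risk/N_sc)` are compared by ordinary
least squares across tissues, with time measured in stem-cell generations
`t = log₂(N_sc) + m_sc·age`:

* **Brownian (small steps):** `ln(D√t/R) − 2(R/(D√t))²` — escape
  probability `Erfc(√(2/t)·R/D)`, computed on the log scale because it
  underflows catastrophically for real tissues;
* **Lévy (rare jumps, tail exponent ν = 2):** `ln(D·t/R)` — a single
  jump clears the gap with probability `(D/R)^(ν−1)`.

An extra risk score, `ERS = (risk/N_sc) / (a_ref·(t₀ + m_sc·age))` with
`a_ref = 2×10⁻¹⁴`, rescales observed risks by expected replication
counts; values in `1 < ERS < 6` are compatible with baseline jump rates.

The package ships a compiled parameter table for 15 TCGA cancer types
(PC1 geometry for all, stem-cell counts, turnover rates and registry
lifetime risks for 8), a cohort geometry stage for computing `x̄₁`, `Rₙ`,
`Rₜ`, `D` from a labelled expression matrix, a seedable first-passage
ensemble simulator that validates the closed forms, and synthetic-data
generators with planted parameters.

## Worked example

```r
library(levyrisk)

tab <- tissue_parameters()      # 15 tissues, 8 with complete risk data
fit_risk_model(tab, "levy")
#> <risk_fit> levy model, n = 8
#>   slope = 0.8229, intercept = -22.34
#>   pearson_r = 0.711, r_squared = 0.505, p = 0.0481

fit_risk_model(tab, "brownian")
#> <risk_fit> brownian model, n = 8
#>   slope = 2.175e-05, intercept = -22.52
#>   pearson_r = 0.518, r_squared = 0.268, p = 0.189
```

The Lévy regression has slope near one (0.82): the observed risks scale
with `D·t/R` as the rare-jump model predicts, and the negative intercept
is the log of the small effective jump rate. The Brownian slope is four
orders of magnitude smaller — a flat line — so small-amplitude expression
noise cannot account for the risk; this contrast is the model's central
result. Scoring the complete tissues:

```r
comp <- complete_rows(tab)
round(setNames(ers_score(comp$risk, comp$n_sc, comp$m_sc), comp$tissue), 2)
#>   BRCA   COAD   ESCA   HNSC   LIHC   LUAD   PRAD   THCA
#>   1.41   1.82  11.57  24.05   0.63  18.44 121.98 118.27
```

Breast and colon sit inside the baseline band (`1 < ERS < 6`); thyroid
and prostate exceed it hundredfold, flagging tissue-specific enhancement
of the effective jump rate. (Scores computed from this table's registry
risks; other risk compilations give other values.)

The simulator reproduces the one-jump closed form
`escape ≈ ½·μ·t·(D/R)`:

```r
cfg <- sim_config(d_scale = 1, r_walk = 100, mu = 1e-4, nu = 2,
                  n_walkers = 1e5, n_generations = 1000, seed = 2)
run_ensemble(cfg)$escape_fraction   # predicted: 5e-4
#> [1] 5e-04
```

See `vignette("levy-risk-model")` for the model's assumptions, numerical
choices and limitations.

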