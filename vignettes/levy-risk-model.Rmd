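---
title: "A one-dimensional Levy-flight model of lifetime cancer risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A one-dimensional Levy-flight model of lifetime cancer risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(levyrisk)
```

## The model

A small portion of a tissue — one colon crypt, say — defines a *microstate*:
a point in gene expression (GE) space whose coordinates are per-gene log2
fold changes relative to a healthy reference. Across patients, normal
samples form a cloud around the origin and tumor samples a second, distant
cloud. The first principal component (PC1) of the sample covariance is the
axis along which the two clouds separate, so a single coordinate
$x_1 = \hat{\mathbf e}\cdot\mathbf v_1$ tracks progression toward cancer.
The geometry is summarized by four numbers per tissue:

* $\bar x_1$ — the tumor-cloud center along PC1 (`xbar1`),
* $R_n$, $R_t$ — the r.m.s. radii of the normal cloud (about the origin)
  and of the tumor cloud (about its center),
* $D = \max_i |v_{1i}|$ — the largest single-gene loading, which sets the
  scale of a one-generation fluctuation of $x_1$ (`d_scale`).

The minimal distance a microstate must travel from the edge of the normal
cloud to the edge of the tumor cloud is $R = \bar x_1 - R_n - R_t$.

Time is counted in stem-cell generations: $t_0 = \log_2 N_{sc}$ doublings
to build a tissue of $N_{sc}$ stem cells, plus $m_{sc}\cdot\text{age}$
turnover generations over a lifetime (default age 80 years), so
$t = \log_2 N_{sc} + m_{sc}\cdot\text{age}$.

Two transport mechanisms are compared.

**Small steps (Brownian regime).** Each generation perturbs $x_1$ by
$\delta x_1 = D r$ with $r \sim U(-1, 1)$. After $t$ generations the
displacement is approximately Gaussian and the probability of having
diffused past $R$ is $\mathrm{Erfc}(z)$ with $z = \sqrt{2/t}\,R/D$. Taking
logs and multiplying by the number of independent lineages gives the
regression form

$$\ln(\mathrm{risk}/N_{sc}) = \mathrm{const} + \ln(D\sqrt t / R)
  - 2\,(R/(D\sqrt t))^{2},$$

implemented in `brownian_predictor()`. For real tissues $z$ is of order
$10$–$10^2$ and the escape probability underflows double precision, which
is why `brownian_escape_log_probability()` works on the log scale
throughout.

**Rare large jumps (Levy regime).** With a small per-generation rate $\mu$
a microstate takes a jump whose magnitude has a Pareto tail
$\pi(\Delta x_1) \sim |\Delta x_1|^{-\nu}$. The chance that a single jump
clears the gap is $(D/R)^{\nu-1}$ (`levy_tail_probability()`), and at the
default $\nu = 2$ the expected lifetime risk per stem cell is
$\mu' (D/R)\, t$, giving the regression form

$$\ln(\mathrm{risk}/N_{sc}) = \mathrm{const} + \ln(D t / R),$$

implemented in `levy_predictor()`. The constant absorbs $\mu'$ and all
normalizations and must be negative if jumps are rare.

On the packaged eight-tissue table the Levy regression has slope near one
while the Brownian regression is flat by three to four orders of magnitude
— small-amplitude expression noise cannot carry a microstate across the
inter-cloud gap within a lifetime, rare collective jumps can:

```{r fits}
fit_risk_model(tissue_parameters(), "levy")
fit_risk_model(tissue_parameters(), "brownian")
```

The **extra risk score** rescales an observed risk by the expected
replication count, $\mathrm{ERS} = (\mathrm{risk}/N_{sc}) /
(a_\mathrm{ref}\,(t_0 + m_{sc}\,\mathrm{age}))$ with
$a_\mathrm{ref} = 2\times10^{-14}$ per generation. Tissues whose risk is
explained by baseline replication noise fall in the band
$1 < \mathrm{ERS} < 6$; large excursions flag viral/genetic enhancement or
immune-related suppression of the effective jump rate.

## The time variable

The total clock $t = t_0 + m_{sc}\cdot\text{age}$ includes the
developmental doublings $t_0$; this matters for tissues with huge stem-cell
pools but slow turnover (lung: $t_0 \approx 30$ versus
$m_{sc}\cdot 80 = 5.6$). Independent recomputation from the packaged table
shows that only this convention reproduces all three reference slopes
(0.82 for the Levy fit, $2.1\times10^{-5}$ and $1.5\times10^{-4}$ for the
Brownian fits); counting lifetime turnover alone gives a Levy slope of
0.56. Both conventions are exposed through the `time_convention` argument
(`"with-t0"`, the default, and `"msc-only"`).

A related caveat: the reported Pearson correlation of the Levy fit is
`r round(fit_risk_model(tissue_parameters(), "levy")$pearson_r, 2)`
($r^2 \approx 0.51$, $p \approx 0.048$) under both the unweighted and the
dev-weighted variants; the package reports what it computes and makes no
claim beyond it.

## Parameters that matter

| Parameter | Meaning | Units | Default |
|---|---|---|---|
| `d_scale` (D) | one-generation fluctuation scale; also the Pareto jump minimum | PC1 units | from data/table |
| `r_walk` (R) | minimal walk length between cloud edges | PC1 units | `xbar1 - rn - rt` |
| `n_sc`, `m_sc` | stem-cell count and turnover rate | count, 1/year | from table |
| `age` | exposure age | years | 80 |
| `nu` | Pareto tail exponent | — | 2 (observed tails fall in 1.6–2.0) |
| `mu` | per-generation large-jump rate | 1/generation | unknown; absorbed into the fit intercept |
| `a_ref` | ERS reference rate | 1/generation | `2e-14` |
| `pseudocount` | added before the geometric-mean reference | expression units | 0 |

The tail formulas assume $R \gg D$; `model_params()` warns when
$R/D \le 10$.

## Numerical choices

* **Log-scale Erfc.** `ln_erfc()` uses the exact log-scale normal tail
  (`pnorm(..., log.p = TRUE)`) for $z \le 25$ and the asymptotic expansion
  $-z^2 - \ln(\sqrt\pi z) + \ln(1 - \tfrac1{2z^2} + \tfrac3{4z^4})$ beyond;
  the two branches agree to better than $10^{-10}$ relative at the switch,
  and both match a scaled quadrature oracle to $10^{-8}$ relative on
  $z \in [0, 30]$.
* **PCA centering.** The covariance is centered on the grand mean of all
  samples (standard PCA), but projections are *uncentered* dot products
  $\hat{\mathbf e}\cdot\mathbf v_1$, so the origin remains the
  normal-cloud center (the reference is a geometric mean over normals, so
  normal log fold changes average to zero gene-wise). For balanced,
  well-separated clouds the two centerings differ negligibly. $R_n$ is
  measured about the origin, $R_t$ about the tumor mean; both are
  one-dimensional radii along PC1, consistent with a one-dimensional model.
* **Sign and ties.** $\mathbf v_1$ is oriented so the mean tumor projection
  is positive (without labels: so its largest-magnitude component is
  positive); the same rule breaks exact eigenvalue ties deterministically.
* **Zeros.** At pseudocount 0, genes with a zero in the normal set have no
  geometric-mean reference and are excluded with a warning, as are genes
  whose log fold change is non-finite because of zeros elsewhere; a
  positive pseudocount retains them.
* **Pareto normalization.** The unnormalized tail integral
  $D\int_R^\infty x^{-\nu}dx$ is implemented as the proper Pareto survival
  $(D/R)^{\nu-1}$ with minimum $D$; the constant of proportionality is
  absorbed into the effective rate $\mu'$, exactly where the regression
  intercept absorbs it.
* **Risk clamping.** The Levy risk estimate is linear and unbounded;
  `levy_risk()` clamps at 1 with a warning rather than failing.

## The simulator

`run_ensemble()` evolves walkers from the origin: per generation a uniform
step $D\,U(-1,1)$, then with probability $\mu$ a Pareto$(D, \nu)$ jump,
two-sided by default (sign $\pm$ with probability $\tfrac12$ — hence the
explicit factor $\tfrac12$ when comparing against one-sided closed forms).
A walker is absorbed the first generation $x_1 \ge R$ (checked after the
jump substep, 0-based indices); there is no reflecting barrier on the
normal side and no fitness landscape — the walk is free until absorption.

Two variance conventions coexist deliberately: the simulator's per-step
variance is $D^2/3$ (uniform steps), while the closed-form Gaussian uses
$a = 2/(D^2 t)$, i.e. variance $D^2 t/4$. Their ratio, $4/3$, is asserted
in the tests; the regression predictors are insensitive to it because it
moves only the constant.

Validity regime of the one-jump closed form
$\text{escape} \approx \tfrac12 \mu t (D/R)^{\nu-1}$: it requires both
$\mu t (D/R)^{\nu-1} \ll 1$ *and* a boundary far outside the diffusive
range ($R \gg D\sqrt{t/3}$), otherwise small-step first passage
contributes measurably. The simulator–formula tests therefore run at
$R/D \ge 100$ with horizons keeping the boundary at $\ge 5$ diffusive
standard deviations.

## What the synthetic generators emulate — and what they do not

`generate_cohort()` plants a two-cloud geometry: normal cloud centered
exactly at the origin (the along-axis draws are re-centered in-sample, so
the planted offset is exact and estimator bias is not confounded with
sampling noise), tumor cloud displaced by `planted_xbar1` along a planted
unit direction, with along-axis radii `planted_rn`/`planted_rt`, isotropic
off-axis noise, an optional Pareto-tailed gene fraction, and optional zero
injection. Expression is reconstructed as $e = e_\mathrm{ref}\,2^{\hat e}$
with lognormal references, so the geometric-mean reference exists by
construction. It is *not* an RNA-seq simulator: no counts, library sizes,
dispersion, batch structure, or gene–gene correlation beyond the planted
axis. Passing recovery tests therefore demonstrates correctness of the
geometry estimators, not robustness to real sequencing artifacts.

`generate_planted_table()` draws tissue parameters from realistic ranges
(D in 0.04–0.08, R in 25–150 PC1 units, $N_{sc}$ in $10^7$–$3\times10^9$,
$m_{sc}$ in 0.05–80 per year — the span of the packaged table) and sets
risks by the Levy law with chosen slope, negative intercept and Gaussian
scatter, for end-to-end recovery checks of the regression stage.

Test problem sizes: recovery uses 500-gene cohorts with 50 + 50 samples
(radius estimates carry ~10% sampling noise at that size, so the 15%
recovery checks average four cohorts); simulator checks use $10^5$–$4
\times 10^5$ walkers over 400–1000 generations, sized so three standard
errors of the checked statistic sit well inside the claimed agreement.

## Known limitations

* The eight complete tissues are few; the Levy slope is estimated from
  eight points and its intercept conflates $\mu'$, immune clearance and
  normalization.
* $m_{sc}$ is treated as age-independent; its known decline with age is
  outside the model.
* The effective jump rate is assumed tissue-independent in the regression;
  tissue-specific rates are exactly what the ERS quantifies after the fact.
* The geometry stage assumes the supplied expression values are already
  normalized and batch-free; it performs no count normalization.
* Reproducing the packaged table's geometry from raw expression data is
  out of scope; those parameters enter as published values.
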