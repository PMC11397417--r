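---
title: "Comprehensive quality scoring of multi-region medicinal fruit panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comprehensive quality scoring of multi-region medicinal fruit panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoscore)
```

## The problem

Medicinal plant material — here the dried Tibetan fruit E'seguo, collected as
tree-level replicates from a dozen production regions — is characterised by two
panels: eight mineral elements (K, Ca, Zn, Mg, Cu, Fe, Se, Mn; ICP-MS) and six
quality/medicinal indicators (total polysaccharide, total acid, the sugar-acid
ratio, total polyphenols, L-malic acid and the vitamin-C glycoside
AA-2&beta;G). The analytical question is how to turn 14 correlated,
mixed-unit measurements into a defensible *ranking of regions by overall
quality*, together with the supporting statistics a survey of this kind
reports: descriptive summaries, group comparisons, correlation structure, a
Mantel test tying the two panels together, and a cluster structure over
regions.

`phytoscore` implements that workflow end to end, plus a synthetic-data
generator that stands in for the unreleased raw measurements.

## The model

### Composite scoring

Let $X$ be the $n \times p$ matrix of *region means* of the quality panel
($n = 12$, $p = 6$ by default). Columns are standardized to $Z$ (sample SD,
$n-1$). PCA is performed on the correlation matrix $R = \mathrm{cor}(Z)$ with
eigenpairs $(\lambda_k, e_k)$:

* factor loadings $a_{jk} = e_{jk}\sqrt{\lambda_k}$,
* component-score coefficients (CSC) $w_{jk} = a_{jk}/\sqrt{\lambda_k} = e_{jk}$,
* variance contribution $v_k = 100\,\lambda_k/p$.

Component scores are $H_{rk} = \sum_j Z_{rj} w_{jk}$; by construction each
$H_k$ column has sample mean 0 and sample variance $\lambda_k$ — the identity
that pins the analysis to region level (only with $n = 12$ region scores and
an $n-1$ denominator does the variance of the first score column equal the
first eigenvalue).

The comprehensive score weights the $k$ retained components by their
*unrounded* normalized variance contributions,
$H_0 = \sum_{k} \frac{v_k}{\sum_{k' \le k_\mathrm{ret}} v_{k'}} H_k$,
and regions are ranked by descending $H_0$ (ties broken by region code and
flagged). Unrounded weights are the default because they reproduce a
published three-component score table to three decimals, while two-decimal
weights (0.63/0.27/0.10-style) do not; `rounded_weights = TRUE` reproduces a
printed formula literally.

Eigenvector signs are fixed by orienting each component so its
largest-|loading| entry is positive. Published tables follow no stated sign
rule, so a per-component flip may be needed to match them; nothing downstream
depends on the choice because a sign flip propagates consistently through
loadings, CSC and scores.

### Group comparison

Per variable, a one-way fixed-effects ANOVA across regions is followed by
Duncan's new multiple range test: means are sorted descending, and means $p$
ranks apart differ when their gap exceeds
$R_p = q_{1-\alpha_p}(p, \mathrm{df}_W)\sqrt{\mathrm{MSE}/n_h}$ with Duncan's
protection level $\alpha_p = 1-(1-\alpha)^{p-1}$, $q$ the studentized-range
quantile and $n_h$ the harmonic mean of the two group sizes (the design is
balanced at $n = 4$, but unbalanced groups are handled). A sub-range of a
non-significant range is never declared significant (step-down protection),
which makes the non-significance relation interval-shaped; compact letters
are the maximal non-significant spans, assigned a, b, c, … in order of
descending means. Note that Duncan's procedure controls the *per-comparison*
protection level, not the familywise error: under a complete null with $k$
groups the probability of any separation is exactly
$1-(1-\alpha)^{k-1}$ (about 0.23 for $k=6$ at $\alpha = 0.05$), and the test
suite asserts precisely that.

### Association structure

Pearson correlation matrices carry two-tailed p-values from
$t = r\sqrt{(n-2)/(1-r^2)}$ and stars at 0.05/0.01/0.001 with no
multiple-testing correction by default (matching the survey presentation;
Holm is available). The Mantel test correlates the off-diagonal entries of
two distance matrices — Bray–Curtis
$d_{ij} = \sum|x_i-x_j| / \sum(x_i+x_j)$ on the mineral panel vs Euclidean on
a quality variable by default, since the source analysis names both metrics
without assigning them — and permutes rows/columns of the second matrix
jointly: $p = (1 + \#\{r_\pi \ge r_\mathrm{obs}\})/(B+1)$, one-tailed
positive, $B = 999$ by default, seed mandatory. Hierarchical clustering is
complete-linkage on Euclidean distances (the standard `stats::hclust`
algorithm), whose merge heights are monotone.

## The synthetic generator: a stated world

The raw replicate-level data behind the motivating survey were never
deposited, so the generator emulates the *published* design and summaries,
and every downstream test is honest about what that establishes:

* **Design**: 12 regions × 4 tree-level replicates, 14 variables.
* **Region means**: uniform draws inside each variable's published
  region-mean range (e.g. K 3.89–5.44 g/kg, total polysaccharide
  16.35–38.50%).
* **Noise**: multiplicative Gaussian, $x = \mu_r(1 + \mathrm{CV}/100 \cdot z)$,
  floored at $10^{-6}$; chosen because the survey reports CVs and all
  variables are positive concentrations. A lognormal option exists. The
  published CVs pool within- and between-region variation, so using them as
  within-region CVs *overstates* replicate noise — conservative for recovery
  tests.
* **Correlation**: the published pairwise Pearson values (e.g. total
  acid–AA-2&beta;G 0.83, total acid–sugar-acid-ratio −0.86, Zn–Se 0.72,
  Cu–Fe −0.59) seed a target matrix that is repaired to the nearest positive
  semi-definite correlation (eigenvalues clipped at $10^{-8}$, diagonal
  renormalized — deterministic). The repair moves some entries (Zn–Se
  0.72 → 0.68): published matrices assembled pairwise need not be jointly
  consistent. Correlation is imposed on the within-region noise via a
  Cholesky factor; the published values mix within- and between-region
  sources, so both regimes (replicates vs region means) are available to the
  analyst.

What a green test does **not** establish: agreement with the survey's
descriptive values, mineral PCA percentages (47.72/25.10) or printed
correlation figures — those depend on the unreleased data. The only direct
checks against published numbers are the internal-consistency identities of
the eigen/score tables (`reference_survey()`), which need no raw data.

### Planted orderings and `effect_size`

`plant_ordering()` places the quality-panel region means on an equally spaced
monotone grid *inside each variable's published range* and derives the
within-region SD as (per-step gap)/`effect_size`, so `effect_size` is exactly
the signal-to-noise ratio of one rank step. This resolves a genuine tension in
the design space: a gradient of 3 SDs per step across 12 regions at the
published CVs cannot stay inside the published (positive) ranges, and we
judged "planted means remain in the stated ranges" the more fundamental
contract. `effect_size = 0` plants nothing and flags the true order as
undefined; large `effect_size` is the zero-noise limit.

## Numerical choices

* CV, SE and all variances use sample ($n-1$) denominators; medians of
  even-length series are midpoint averages.
* The sugar-acid ratio is computed per replicate, then summarized (the
  published ratio *range* is incompatible with a single ratio of means).
* Eigenvalues below $10^{-12}$ are clamped to 0; correlation-matrix PCA is
  forced (not covariance) by the mixed units and by $\sum_k \lambda_k = p$.
* Mantel and the simulator take mandatory seeds; package code saves and
  restores the caller's RNG state, so library calls never perturb a session's
  random stream.
* Degenerate inputs fail loudly and specifically: zero-variance columns,
  groups with a single replicate, negative Bray–Curtis input, constant
  distance matrices, total acid ≤ 0.

## Known limitations

* Units are opaque labels, never converted; the source material is internally
  inconsistent about mineral scales (g/kg vs µg/kg) and no conversion is safe.
* No factor rotation, no partial Mantel, no Tukey/Bonferroni suite (Holm on
  correlation p-values is the one adjustment offered).
* Calibration helpers cover the linear standard-curve math only, not the
  chromatography.
* The generator does not emulate spatial/watershed covariance, species
  effects or instrument drift; region means are exchangeable draws.
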