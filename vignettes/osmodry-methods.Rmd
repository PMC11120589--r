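---
title: "Methods: response analysis of osmotic dehydration experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: response analysis of osmotic dehydration experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmodry)
```

## The experiment and its data

Osmotic dehydration (OD) removes water from plant tissue by immersing it
in a hypertonic solution — here beetroot cubes in sugar beet molasses.
Water leaves the tissue while solutes (sugars, minerals, betaine,
phenolics) enter, so the treatment simultaneously dries the product and
enriches it. Three process factors control the outcome: bath temperature
`T` (°C), molasses concentration `Conc` (% mass) and immersion time `t`
(h). The packaged experiment varies them over a 3-level Box–Behnken
design (BBD): 12 runs at the edge midpoints of the factor cube plus 3
replicated center points, 15 runs in all, each characterized by 13
responses — the three dehydration indices (DMC, WL, SG), four minerals
(Mg, K, Na, Ca), two radical-scavenging IC50 values (DPPH, ABTS),
flavonoids, phenols, titratable acidity and betaine.

The fixture (`load_design_table("table1")`) stores the per-run means and
standard deviations as published; replicate-level raw data were never
released, so every statistic in this package operates on the 15 means.
Units are carried as column metadata. Two unit conventions circulate for
the minerals (mg/kg in the run-table header, mg/100 g in the narrative
that accompanies it); the fixture records the header unit verbatim and
does not attempt to resolve the discrepancy.

## Dehydration indices

For a sample with fresh mass $m_i$, post-treatment mass $m_f$,
dry-matter mass $m_d$, and water/dry-matter mass fractions $z, s$
(with $z + s = 1$ in each state):

$$\mathrm{WL} = \frac{m_i z_i - m_f z_f}{m_i}, \qquad
  \mathrm{SG} = \frac{m_f s_f - m_i s_i}{m_i}, \qquad
  \mathrm{DMC} = 100\,\frac{m_d}{m},$$

WL and SG in g per g of fresh sample. The DMC denominator $m$ is a
convention choice: gravimetric oven-drying reports dry matter per
*measured* (post-treatment) mass $m_f$, while some balance formulations
divide by the *fresh* mass $m_i$. Dehydrated-sample DMC values of 17–50 %
are only arithmetically consistent with the measured-mass basis, so
`compute_dmc()` defaults to `basis = "measured"` and exposes `"fresh"`
explicitly. Because $z + s = 1$ holds in both states, WL and SG are tied
to the overall mass change by $\mathrm{WL} - \mathrm{SG} = (m_i - m_f)/m_i$;
`mass_balance_check()` verifies this identity (default tolerance
$10^{-9}$) and is the cheapest way to catch transcription errors in
mass-balance tables.

## Standard-score ranking

Choosing the best run is a multi-criteria problem: 13 responses in
incompatible units, some to be maximized, some minimized. Each criterion
column is min–max normalized against its own extremes,

$$s = \frac{x - x_{\min}}{x_{\max} - x_{\min}} \ \text{(benefit)}, \qquad
  s = \frac{x_{\max} - x}{x_{\max} - x_{\min}} \ \text{(cost)},$$

so the preferable extreme always scores 1, and the standard score SS of
a run is the arithmetic mean of its 13 normalized scores. Defining SS as
the mean (rather than the raw sum) keeps it in $[0, 1]$, where a score
approaching 1 flags a run near-optimal on all criteria at once. Exact SS
ties — which occur for identical center replicates on noise-free
synthetic tables — are broken by run id, with a warning.

The benefit/cost split is a modelling input, not a measured fact.
The package default treats DPPH and ABTS as costs (they are IC50 values:
the extract concentration needed to quench half the radical pool, so
*lower* means a stronger antioxidant) and titratable acidity as a cost
(the declared optimum run holds the column minimum), with the remaining
ten criteria as benefits. The directions are a named vector argument, so
any other assignment is a one-line override.

```{r}
design <- load_design_table("table1")
scores <- standard_scores(design)
scores[scores$rank == 1, c("run", "SS")]
```

Run 8 (60 °C, 70 %, 5 h) is the unique argmax with SS = 0.859. The
source study prints 0.847 for the same run; with equal weights and
mean-of-scores the printed table yields 0.859, and since neither the
direction table, weights nor rounding of the original computation were
disclosed, the package reports its own honestly computed value rather
than tuning the direction set until the printed one appears.

## Multivariate characterization

**Correlation.** `pearson_matrix()` computes product-moment correlations
over the 15 run means with two-sided p-values from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n - 2$ degrees of freedom. No
multiple-testing correction is applied, matching the descriptive use of
the matrix; with 78 pairs at $n = 15$ the individual p-values should be
read as exploratory.

**Clustering.** `cluster_runs()` performs complete-linkage agglomeration
on city-block (Manhattan) distances between the *raw* response vectors.
Raw units are deliberate: potassium and sodium live in the thousands of
mg/kg and dominate the distance sums, which is what places the top
linkage heights near 16,000–18,000 and groups runs chiefly by their
mineral load; z-scoring first would give a different, more balanced
geometry. Complete linkage is monotone, so merge heights never decrease.

**PCA.** `pca_correlation()` z-scores every column and eigendecomposes
the correlation matrix. Correlation-matrix PCA is the only defensible
choice for these heterogeneously scaled responses — covariance PCA would
assign essentially all variance to K and Na. Loadings are orthonormal
eigenvectors (so `loadings %*% diag(eigenvalues) %*% t(loadings)`
reconstructs the correlation matrix), each component's sign is fixed by
making its largest-magnitude loading positive, and a variable's
contribution to a component is its squared loading in percent.

On the packaged table these tools give PC1 = 62.8 %, PC1+PC2 = 80.7 %,
and a k = 4 cut whose largest-mineral cluster is {4, 12} ∪ {8, 11}
rather than a single {4, 8, 11, 12} group. The source study reports
52.13 %/72.0 % and slightly different memberships; those figures are not
reproducible from the printed run table under any preprocessing we
examined, and at least one printed cell (run 2's K, whose standard
deviation exceeds half its mean) is internally implausible. The package
computes from the table as printed and leaves the discrepancy visible.

## Perceptron response models

Each response is modelled by a 3–H–1 multilayer perceptron
$y = f_{\mathrm{out}}(W_2\, f_{\mathrm{hid}}(W_1 x + B_1) + B_2)$ on
min–max normalized inputs and output (bounds from the training rows
only; the inverse transform is exact on the bounds). The hidden bias
$B_1$ sits inside the hidden activation — the standard composition — so
the hidden layer is not left biasless. Available activations are
identity, logistic, tanh and exponential; training defaults to tanh
hidden / identity output, a robust pairing for smooth response surfaces
on a bounded design.

Training minimizes the training-split sum of squares with BFGS
(`stats::optim`, analytic backprop gradient, relative tolerance
$10^{-12}$, 200-iteration cap — the batch analogue of the epoch caps
used by GUI neural tools). Because a 15-row problem is riddled with
local minima, each hidden size in the searched range (default 3–10,
the union of the ranges that practice suggests for this data size) is
restarted from 50 random initializations; restarts with non-finite loss
are discarded and counted. The 15 runs are split 60/20/20 into
train/test/validation (9/3/3 by the round-train, round-test,
remainder-validates rule) by a seeded shuffle without stratification,
so center replicates may land in any split. The retained model is the
one with the highest test-split $r^2$; the validation split is reported
but never used for selection. All randomness flows from the single
config seed, so fits are exactly reproducible.

## Sensitivity and goodness of fit

Yoon's interpretation method reads factor influence directly off the
trained weights:

$$RI_i = \frac{\sum_k w_{ik} w_{k}}{\sum_i \left|\sum_k w_{ik} w_{k}\right|} \cdot 100\,\%$$

with $w_{ik}$ the input-to-hidden and $w_k$ the hidden-to-output
weights; biases are excluded and the weights are taken on the normalized
scale on which the network was trained, so the signed importances of the
three factors always satisfy $\sum_i |RI_i| = 100$ and are invariant to
rescaling a whole layer by a positive constant.

`gof_report()` evaluates reduced $\chi^2$, RMSE, MBE, MPE, SSE, AARD and
$r^2$, plus residual moments. Two deliberate conventions: (1) MPE as
printed in the food-drying literature,
$\frac{100}{N}\sum |x_{exp}-x_{pre}|/x_{pre}$, is the same number as
AARD whenever predictions are positive — both are implemented verbatim
and both reported, rather than silently "fixing" MPE to its signed
textbook form; (2) skewness and kurtosis are plain moment estimators
(no small-sample bias correction), with kurtosis in excess form so a
normal residual spectrum reads 0. The $\chi^2$ denominator uses the
model's free-parameter count $5H + 1$ by default; with $N = 15$ and
$H \ge 3$ this makes $N - n \le 0$ and $\chi^2$ is reported as `NA`
with a warning rather than as a negative number.

## Synthetic ground truth

`bbd_design()` + `simulate_responses()` generate BBD tables from
quadratic surfaces defined on the *coded* (−1, 0, +1) factors, so a
coefficient's sign is the ground-truth effect direction — exactly what a
sensitivity method must recover. The default surface bundle mimics the
packaged experiment qualitatively (indices, minerals and betaine rising
with temperature and time; IC50s and acidity falling) with magnitudes
and noise levels of the observed order, so the synthetic optimum lands
at the high-temperature/long-time corner as in the real data. What the
generator does *not* emulate: replicate-level noise hierarchies,
non-Gaussian measurement error, and the correlated (common-cause) noise
across responses of a real experiment — so passing recovery tests show
the pipeline's correctness, not robustness to those real-data features.

Sizes were chosen to keep the full validation suite fast: sensitivity
sign-recovery uses 20 seeded repeats of a 15-run table with 5 restarts
each, and the packaged-table training checks search H = 3–10 with 50
restarts; the complete test suite runs in well under a minute.

## Known limitations

* All inference operates on the 15 printed run means; measurement sds
  are carried but not propagated.
* The printed run table is internally inconsistent with the source
  study's own multivariate figures (see above); the package sides with
  the table.
* The 3-row test split makes the model-selection $r^2$ a high-variance
  criterion; restarts mitigate but do not remove this.
* No kinetic or diffusion modelling of the osmotic process is attempted,
  and no alternative multi-criteria schemes (TOPSIS, AHP) or
  weight-based importance variants (Garson, Olden) are provided.
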