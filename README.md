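# osmodry

Analysis toolkit for osmotic dehydration experiments laid out as
three-factor Box–Behnken designs. Osmotic dehydration immerses plant
tissue (here: beetroot cubes) in a hypertonic solution (sugar beet
molasses) so that water leaves the tissue while sugars, minerals,
betaine and phenolics enter; the practical question is which combination
of bath temperature *T*, solution concentration *Conc* and immersion
time *t* yields the best semi-product.

The package covers the full analysis chain for such experiments:

* **Dehydration indices** from mass balances — dry matter content
  `DMC = 100·m_d/m`, water loss `WL = (m_i·z_i − m_f·z_f)/m_i`, solid
  gain `SG = (m_f·s_f − m_i·s_i)/m_i` — with the mass-balance identity
  `WL − SG = (m_i − m_f)/m_i` as a built-in consistency check.
* **Multi-criteria ranking**: each response column is min–max
  normalized toward its preferable extreme (benefit: `(x−min)/(max−min)`,
  cost: `(max−x)/(max−min)`), and the standard score SS of a run is the
  mean of its normalized scores; the run maximizing SS is the
  recommended processing condition.
* **Multivariate characterization**: Pearson correlation matrix with
  t-based p-values, complete-linkage clustering on city-block distances
  over the raw response vectors, and correlation-matrix PCA with
  variance decomposition and squared-loading variable contributions.
* **Perceptron response models**: 3–H–1 networks
  `y = f_out(W2·f_hid(W1·x + B1) + B2)` on min–max normalized data,
  trained by BFGS with seeded random restarts and hidden-size search,
  60/20/20 train/test/validation splitting, selection by test-split r².
* **Sensitivity and fit diagnostics**: Yoon's connection-weight
  relative importance `RI_i = Σ_k(w_ik·w_k) / Σ_i|Σ_k(w_ik·w_k)| · 100 %`
  (signed, absolute values summing to 100 % per response), and a
  goodness-of-fit suite (reduced χ², RMSE, MBE, MPE, SSE, AARD, r²,
  residual moments).
* **Synthetic ground truth**: a Box–Behnken generator with quadratic
  response surfaces on coded factors plus Gaussian noise, for validating
  every stage against known effect directions.

The 15-run beetroot experiment (13 responses, means ± sd) and its
28-day storage-stability series ship as plain-text fixtures.

## Worked example

```r
library(osmodry)

design <- load_design_table("table1")
scores <- standard_scores(design)
scores[scores$rank == 1, c("run", "SS")]
#>   run        SS
#> 8   8 0.8588753
```

Run 8 — 60 °C, 70 % molasses, 5 h — is the unique standard-score
optimum: it holds the best values of DMC, solid gain, Ca, both IC50s,
flavonoids, phenols, acidity and betaine simultaneously, so its mean
normalized score (0.859) towers over the next run. The multivariate
view of the same table:

```r
ct <- pearson_matrix(design)
round(ct$r["DMC", "Ca"], 3)
#> [1] 0.927

p <- pca_correlation(design)
round(p$percent_variance[1:2], 2)
#> [1] 62.79 17.93

cluster_runs(design, k = 4)
#> complete-linkage clustering (cityblock distance), k = 4
#>   cluster 1: 1, 2, 5, 6, 9, 10
#>   cluster 2: 3, 7, 13, 14, 15
#>   cluster 3: 4, 12
#>   cluster 4: 8, 11
```

The clusters separate the runs by their mineral load (city-block
distances on raw units are dominated by K and Na), isolating the
long-time, high-uptake runs {4, 8, 11, 12} in the two top clusters.
The whole chain, including the (slower) perceptron stage, runs with:

```r
res <- run_pipeline(pipeline_config(input = "table1", ann = TRUE, seed = 1))
res$summary$optimal_run
#> [1] 8
```

which writes `scores.csv`, `correlations.csv`, `clusters.json`,
`pca.csv`, `ann_models.json`, `fit_report.csv`, `ri_matrix.csv` and
`summary.json` to the configured output directory.

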