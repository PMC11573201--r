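# clonedyn

Stochastic modeling and inference for clonal growth heterogeneity in
cultured epithelial cells.

When epithelial cells are seeded sparsely and left to grow into clones,
final clone sizes are wildly heterogeneous: a minority (~10%) of clones
keeps expanding exponentially while the rest stall at small sizes. This
package implements the quantitative machinery to dissect that
heterogeneity:

* **Two-state stochastic growth model.** Each proliferative cell `X`
  divides at rate `g` (`X → 2X`) or irreversibly arrests at rate `k`
  (`X → Y`), with no death and no re-entry. Exact Gillespie simulation of
  clones and ensembles, with an optional carrying capacity `K` that makes
  the division rate logistic in total clone size (`Rcpp` core).
* **Distribution-matching inference.** A `(g, k)` parameter sweep scores
  simulated clone-size distributions against observed ones with the
  two-sample Kolmogorov–Smirnov statistic on log2 sizes ("division
  counts") and selects the best-fitting rates.
* **Growth ODE fitting.** Mean-field exponential
  (`dX/dt = (g−k)X`, `dY/dt = kX`) and logistic-growth-rate
  (`dX/dt = gX(1−N/K) − kX`) models, fitted to mean growth curves by
  bounded Levenberg–Marquardt least squares with multi-start.
* **Modality analysis.** Sarle's bimodality coefficient with the 5/9
  (bimodal) and 1/3 (unimodal) thresholds, and Gaussian mixture models
  with BIC component selection.
* **Barcode heritability analysis.** Expansion-and-split simulations of
  DNA-barcoded populations, top-decile overlap and abundance correlation
  between split samples, spike-in (50/500/1000-cell) reads-to-cells
  calibration, and replicated non-heritable nulls under unimodal, bimodal
  and stochastic growth-rate laws.
* **Synthetic-data generators** for study-shaped clone tables, barcode
  experiments and plating-density series, so every stage runs end to end
  without external data.

## Worked example

```r
library(clonedyn)

## a synthetic day-8 plate: 10% exponential clones (g = 0.75, k = 0),
## 90% arrest-prone clones (g = 0.7, k = 0.3)
cfg <- synthetic_config(seed = 1)
clones <- gen_clone_size_table(cfg, days = 8)
table(classify_proliferative(clones$n_cells))
#> highly_proliferative   less_proliferative
#>                   50                  450

## infer (g, k) for the arrest-prone class from its size distribution
obs <- clone_size_sample(
  clones$n_cells[clones$condition == "less_proliferative"], day = 8)
parameter_sweep(obs, n_sim_clones = 500, seed = 2)
#> KS parameter sweep over 21 x 21 grid ( 500 clones/point, day 8 )
#>   best fit: g = 0.7 , k = 0.35 | KS = 0.0556 , p = 0.458

## split-sample heritability: a heritable barcode experiment against a
## non-heritable null
ref <- log2_divisions(clones$n_cells, drop_singletons = TRUE)
ex <- simulate_split_experiment(
  1000, growth_dist = growth_rate_dist("stochastic", ref),
  heritable = TRUE, seed = 3)
null_distribution(ex$counts$cells_a, ex$counts$cells_b, reference = ref,
                  kind = "stochastic", n_replicates = 200, seed = 4)
#> Heritability analysis (stochastic null, 200 replicates, 1000 barcodes)
#>   observed: r = 0.856 | top-decile overlap = 0.81
#>   empirical p (r) = 0.00498 | empirical p (overlap) = 0.00498
#>   null: mean r = -0.0217 | mean overlap = 0.0881
```

The sweep recovers the generating rates (truth `g = 0.7`, `k = 0.3`;
plateaus along compensating `(g, k)` directions make one-grid-step
excursions like `k = 0.35` expected). The heritable barcode experiment
shows a split-sample correlation of 0.86 and 81% top-decile overlap, far
outside a non-heritable null whose correlation is centred near zero and
whose overlap sits at the ~10% chance level.

## The analysis workflow

Numbered drivers under `analysis/` run the full study-shaped workflow on
synthetic data, writing tables under `results/`:

1. `01_simulate_clones.R` — multi-day clone-size table and summaries
2. `02_sweep_inference.R` — per-class KS parameter sweeps at day 8
3. `03_ode_fits.R` — exponential and logistic growth-curve fits
4. `04_modality.R` — bimodality coefficients and GMM fits per day
5. `05_heritability.R` — barcode split experiment, spike-in calibration,
   and the three non-heritable nulls

Run them in order with `Rscript analysis/01_simulate_clones.R`, etc.
`run_pipeline()` performs the same stages programmatically and writes a
JSON manifest with output digests; identical configs reproduce outputs
byte-identically.

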