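# tdaniche

Topological prediction of perivascular niche formation from time series of
tumour and macrophage cell coordinates.

## The problem

In tumour-immune dynamics a lesion can be eliminated, held in equilibrium,
or escape; escape is presaged by *perivascular niches* - blood vessels with
at least 10 tumour cells within 5 length units, the staging ground for
intravasation and metastasis. Given identity-tracked snapshots of cell
locations (tumour / macrophage / vessel, with a continuous macrophage
phenotype p in [0, 1]; p >= 0.5 marks the pro-tumour M2 state), the
question is whether the *spatial arrangement* of cells predicts niche
formation at the final time, earlier and better than classic markers
(tumour count, macrophage count, M1/M2 phenotype ratio, minimum
tumour-vessel distance).

## The method

Each point cloud X (tumour cells T or macrophages M at time t) is
summarised by persistent homology and vectorised as a persistence image -
a grid obtained by summing persistence-weighted Gaussian kernels over the
diagram points in (birth, persistence) coordinates:

* **PI^VR_0(X), PI^VR_1(X)** - Vietoris-Rips filtration: simplices enter
  at their diameter (`d(x, y) <= eps`, closed balls). Dimension 0 tracks
  multi-scale clusters (finite deaths = single-linkage merge heights),
  dimension 1 tracks holes in the cell arrangement.
* **PI^rad_0(T)** - radial filtration: the fixed complex at linkage 0.7 is
  refiltered by `w = R - ||x - mu||` (basepoint mu = (25, 25), R = 35), so
  outermost cells enter first; finite bars are boundary outgrowths
  (tortuosity), infinite bars - the components of the full complex - form
  an appended 1-D profile over radial distance.
* **PI^vin_0(M)** - persistence vineyard: the dimension-0 VR diagrams of
  the 10 snapshots at t-100, ..., t-10 stacked along a time axis, records
  plotted at (slot, death radius).
* **PI^zz_0(M)** - zigzag persistence: fixed-radius complexes (eps = 2) at
  the 10 snapshot times joined by intersection complexes (matched by cell
  id) into the length-19 alternating sequence
  `K(t1) <- K(t1) ∩ K(t2) -> K(t2) <- ...`; the dimension-0 interval
  decomposition records when clusters of identified cells appear, split,
  merge and vanish, and intervals are plotted at (start index, lifetime).

All persistence engines (union-find H0 with the elder rule, GF(2) boundary
reduction for H1, a component-graph interval-decomposition algorithm for
zigzag H0) are implemented in the package, with Rcpp cores.

A binary label (niche present at the final snapshot) is predicted from
each image by L2-regularised logistic regression scored with 10 repeats of
stratified 5-fold cross-validation; the fitted coefficient vector reshapes
back into a signed image that shows which diagram regions drive the
classification. A built-in agent-based caricature
(`simulate_run`, `preset_params`) generates labelled cohorts in the three
regimes for end-to-end evaluation.

## Worked example

```r
library(tdaniche)

cohort <- generate_cohort(10, base_seed = 1)   # 30 runs, 10 per regime
labels <- vapply(cohort$series, label_run, integer(1))
table(cohort$regime, labels)
#>              labels
#>               0  1
#>   elimination 10  0
#>   equilibrium  8  2
#>   escape       0 10

tab <- accuracy_vs_time(cohort$series,
                        tags = c("vr0_M", "zz0_M", "bench_ratio"),
                        times = c(250, 500), seed = 1)
tab
#>   feature_tag time mean_accuracy accuracy_sd baseline folds repeats
#> 1       vr0_M  250     0.9295238  0.09744289      0.6     5      10
#> 2       vr0_M  500     0.8430476  0.12980890      0.6     5      10
#> 3       zz0_M  250     0.8297143  0.13229346      0.6     5      10
#> 4       zz0_M  500     0.7643810  0.16809258      0.6     5      10
#> 5 bench_ratio  250     0.9001905  0.11288402      0.6     5      10
#> 6 bench_ratio  500     0.8181905  0.15358396      0.6     5      10
```

The labels are decided at t = 500, yet the dimension-0 macrophage image
classifies them with ~93% accuracy from the snapshot at t = 250 - half
the simulated horizon, well before tumour cells approach the vessels.
`coefficient_map(attr(tab, "reports")[["vr0_M@500"]])` returns the 20 x 20
signed coefficient grid; `plot_accuracy_vs_time(tab)` draws the
accuracy-versus-time comparison.

Single runs can be written to and read from plain CSV
(`write_cell_table` / `read_cell_table`), and diagrams/images to JSON with
exact round trips (`write_diagram`, `write_image`). A thin command-line
wrapper lives at `inst/scripts/abm-tda`
(`simulate` / `featurise` / `classify` / `report`).

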