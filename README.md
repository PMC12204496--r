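# isletmap

Semi-automated, single-islet histopathology analysis of pancreatic tissue
sections across stages of type 1 diabetes (T1D).

## The problem

T1D destroys the insulin-producing beta cells of pancreatic islets. Tissue
sections stained for eight endocrine hormones (CHGA, ProINS, INS, IAPP,
ProGCG, GCG, SST, PPY) plus the pan-immune marker CD45 carry an enormous
amount of structure — islet architecture, endocrine composition, immune
infiltration (insulitis), and the spatial arrangement of thousands of islets
per slide — but extracting it reproducibly requires an auditable pipeline
rather than manual scoring. `isletmap` implements such a pipeline end to end
for co-registered binary stain masks, a parenchymal boundary polygon
(GeoJSON) and cell point sets (CSV), and ships a synthetic cohort generator
that emulates the statistical structure of real donor cohorts so that every
stage is testable without access to donor material.

## What it computes

* **Islet objects** — connected components of the union of six defining
  stains, holes filled, filtered at a minimum area of 1,000 µm² (≈ 10 cells,
  ≈ 36 µm equivalent diameter) and a 10 µm tissue-border margin; per-islet
  shape descriptors: circularity `4πA/P²`, solidity `A/A_hull`, aspect ratio
  (short/long side of the minimum-area bounding rectangle), equivalent
  diameter `2√(A/π)` and spherical volume `(π/6)d³`.
* **Hormone quantification** — per-islet staining-area fractions for nine
  channels, the endocrine union of the eight hormone stains, Jaccard overlap
  indices for all 56 ordered stain pairs, subset calls at the 1% threshold
  (insulin-deficient islets `ProINS < 1%`, GCG-deficient `GCG < 1%`, PPY/SST
  positivity `≥ 1%`), section summaries (densities, INS:GCG ratio) and
  endocrine mass estimates from regional pancreas weights, plus 14-bin
  log2-size-stratified profiles with exponential fits `y = a·e^{b·log2 A}`.
* **Immune burden** — watershed-partitioned 20 µm peri-islet bands (never
  overlapping), point-in-polygon attribution of CD45⁺ cells and nuclei to
  intra-/peri-islet compartments, CD45-per-nuclei frequencies, and the
  automated consensus insulitis diagnosis (≥ 15 CD45⁺ cells associated with
  each of ≥ 3 islets per donor).
* **Single-islet phenotyping** — a 14-feature matrix (log-transformed raw
  areas + CD45 count + circularity, z-scored), 2-D UMAP embedding
  (`n_neighbors = 50`, `min_dist = 0.1`, `n_epochs = 1000`), two-round DBSCAN
  (ε 0.5 / 50 points, then ε 0.2 / 20 points), semantic mapping of clusters
  onto the vocabulary I, II, III, IV, V-A, V-BC, and a deterministic
  three-stain rule-based key (INS/GCG/CD45, optional PPY).
* **Spatial statistics** — a modified Ripley's K where each islet's neighbor
  count is divided by the fraction of the search circle inside the tissue
  polygon (exact circle–polygon intersection areas) and normalized by the
  slide-average density (K = 1 ⇔ random), fractal dimension (log–log slope,
  radii ≤ 600 µm excluded), Delaunay neighborhood metrics with a 4,000 µm
  edge-pruning radius and the 4 mm / π·16 mm² fallback for neighborless
  islets, cluster-scoped Delaunay at 8 mm with isolated-islet fractions, and
  back-projection map documents.

The geometry, Delaunay triangulation, DBSCAN, kNN and the UMAP optimizer are
implemented in the package itself (C++ via Rcpp) and validated in the test
suite against closed forms, Monte-Carlo oracles and frozen reference values.

## Worked example

```r
library(isletmap)

# 1. synthesize one non-diabetic pancreatic-tail section (6 x 6 mm)
tpl    <- load_stage_template("Ctrl", "PT")
tissue <- generate_tissue(seed = 1, width_mm = 6, height_mm = 6,
                          irregularity = 0.2, donor_id = "demo")
islets <- generate_islets(tpl, tissue, seed = 2)
masks  <- render_stain_masks(islets, pixel_size_um = 2,
                             bbox = c(0, 0, 6000, 6000))
cells  <- generate_cells(islets, tpl, seed = 3)

# 2. segment islet objects from the six defining stains
found <- build_islets(masks[defining_channels()], tissue)
nrow(found)
#> [1] 67
summary(found$area_um2)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>    1080    2008    3112    6013    6978   37688

# 3. hormone quantification and subset calling
prof <- hormone_profiles(found, masks)
subs <- classify_subsets(prof)
colMeans(subs[, -1])
#>           is_IDI is_GCG_deficient  is_PPY_positive  is_SST_positive
#>       0.05970149       0.34328358       0.01492537       0.68656716

# 4. immune burden and insulitis
rec <- attribute_cells(found, cells)$records
rec$donor_id <- "demo"
call_insulitis(rec)$donors
#>   donor_id n_insulitic diagnosis
#> 1     demo           0     FALSE
mean(rec$cd45_total >= 1)
#> [1] 0.3134328

# 5. spatial statistics
curve <- ripley_modified(found[, c("centroid_x_um", "centroid_y_um")], tissue)
round(attr(curve, "auc"))
#> [1] 9373
fractal_dimension(curve)$slope
#> [1] 2.002695
```

Reading the numbers: the section yields 67 islets with the right-skewed size
distribution typical of human pancreas (median ≈ 3,100 µm², mean pulled up by
a few large islets); ~6% are insulin-deficient and ~34% GCG-deficient — the
configured control-stage fractions; no insulitis is called (a healthy donor);
31% of islets carry ≥ 1 CD45⁺ cell; the Ripley AUC near the grid width and a
fractal dimension ≈ 2 indicate spatial randomness, as generated.

`run_pipeline()` chains all stages over a multi-section cohort (see
`synthesize_cohort()`), pools islets for clustering, and writes CSV/JSON
artifacts; `exec/isletmap` exposes the `synth`, `segment`, `quantify`,
`immune`, `cluster`, `spatial` and `run` subcommands.

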