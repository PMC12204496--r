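---
title: "Methods: single-islet histopathology analysis with isletmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-islet histopathology analysis with isletmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`isletmap` reconstructs, as reusable and tested code, a semi-automated
analysis of multiplex-IHC pancreatic tissue sections across type 1 diabetes
(T1D) stages: non-diabetic controls (Ctrl), autoantibody-positive preclinical
donors (AAb), short-duration clinical T1D (T1DS) and longer-duration T1D
(T1DL), each sampled in the pancreatic tail (PT) and head (PH). This
vignette documents the models, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices a maintainer should know about. Empirical claims below are
restricted to quantities the test suite or `scripts/acceptance.R` compute.

## 1. Islet objects

Islets are defined as endocrine cell clusters of at least 1,000 µm²
(roughly 10 cells, 36 µm equivalent diameter). Segmentation
(`build_islets()`) takes the six defining stain masks (CHGA, ProINS, INS,
GCG, SST, PPY), forms the pixel union, labels 8-connected components
(8-connectivity avoids splitting diagonally touching stained regions), fills
interior holes to create contiguous objects, removes components below the
area threshold, and removes objects whose polygon comes within 10 µm of the
tissue boundary (incomplete capture and edge artifacts). Components are
polygonized by marching squares at the 0.5 level (`grDevices::contourLines`
on a zero-padded window), yielding resolution-independent µm-coordinate
polygons; the reported islet *area* is the pixel-count area, which is what a
threshold-based pixel classifier measures.

Shape descriptors: circularity $4\pi A/P^2$, solidity $A/A_{hull}$, and
aspect ratio defined as the short/long side ratio of the minimum-area
bounding rectangle (rotating calipers). The bounding-rectangle definition
was chosen over the raw minimum/maximum Feret-diameter ratio because only it
gives the values one expects of the descriptor — 1 for a square and circle,
0.5 for a 2:1 rectangle (the Feret ratio of a square is $1/\sqrt 2$). Raw
Feret diameters remain available (`feret_diameters()`). All three
descriptors are clamped to $(0, 1]$ against marching-squares perimeter
noise. Diameters and volumes assume circularity/sphericity:
$d = 2\sqrt{A/\pi}$, $V = (\pi/6) d^3$.

Coordinates are physical micrometers with the y axis downward (raster
convention), origin at the tissue bounding-box corner. Point-in-polygon
tests use the closed convention (a point on the boundary is inside) so that
attribution is deterministic.

## 2. Hormone quantification

`hormone_profiles()` rasterizes each islet polygon on the mask grid and
reports, per channel, stained pixels inside the islet over islet pixels. The
endocrine union is the union of all eight hormone stains (CHGA included —
the high-proinsulin channel is a nested sub-mask of total proinsulin, not a
ninth stain in the union). A missing channel raises an error rather than a
silent zero. Jaccard indices and directional double-positive fractions are
reported for all 56 ordered pairs of the eight stains; a pair with an empty
union scores 0 by convention so donor-level means are never poisoned by NaN.

Subset calls use the 1% staining-area threshold with strict inequality for
deficiency and inclusive for positivity, matching the phrasing of each rule:
insulin-deficient islets (IDIs) have `ProINS < 1%`, GCG-deficient islets
`GCG < 1%`, PPY/SST-positive islets `>= 1%`. Mass estimates multiply
relative staining areas by regional pancreas weight; a missing weight
propagates as `NA`, never as zero.

Size-stratified profiles use 14 equal-width bins of $\log_2$(area) spanning
the observed range, and fit $y = a e^{b x}$ to the *bin means* (weighted
fitting on all islets is a possible alternative; bin means match how such
profiles are usually displayed). The fit is least squares via `nls` seeded
by a log-linear regression, falling back to the log-linear estimate if the
iteration fails; $R^2$ on bin means is reported.

## 3. Immune burden and insulitis

Peri-islet regions are the 20 µm expansion bands around islets, partitioned
so bands never overlap: each candidate location belongs to the islet whose
boundary is nearest (a watershed on a fine raster, default 2 µm; exactly
equidistant pixels go to the lower islet id for determinism). Cell
attribution applies the same rule directly to points, so the point rule and
the raster region agree by construction. Frequencies are CD45⁺ cells per
nuclei, with nuclei counts including CD45⁺ cells (they are nucleated cells);
the 0/0 case is defined as 0 and flagged, so islets without detected nuclei
cannot poison means.

The insulitis diagnosis follows the consensus definition: an islet is
insulitic when its total associated CD45⁺ count — intra- plus peri-islet —
reaches 15, and a donor is positive when at least 3 insulitic islets occur
across that donor's analyzed sections. PT and PH sections of one donor are
pooled, consistent with diagnoses that cite islets from both regions.

## 4. Single-islet phenotyping

The feature matrix has 14 columns: natural-log-transformed raw areas (µm²)
of the eight hormone stains, the endocrine union, the islet itself and the
mean Delaunay area, plus the raw CD45⁺ count and circularity. Choices the
source analysis left open:

* **Pseudocount** +1 µm² inside the log — zero hormone areas are the norm in
  IDIs and must map to a finite value ($\ln 1 = 0$).
* **Log base** — natural log; the base only rescales columns that are
  z-scored afterwards, so the choice is immaterial.
* **Population SD** in the z-scores (pooled standardization of a fixed
  dataset, not inference from a sample).
* **CD45 enters raw** — "log-transformed raw areas" covers areas only; the
  count is left untransformed and z-scored.

The UMAP embedding is computed by a compact in-package implementation of the
reference algorithm (exact kNN, smoothed-kNN fuzzy simplicial set, union
symmetrization, sampled attractive/repulsive stochastic gradient descent
with 5 negative samples per positive) because no UMAP implementation exists
in the supported R environment. Two deviations from the reference are
deliberate: initialization is PCA per connected component of the kNN graph,
components laid out on a coarse grid — disconnected components share no
attractive edges, so a tangled random or global-PCA start could never be
repaired — and the optimizer uses its own xorshift RNG so a seed fully
determines the embedding on one platform. On identical feature matrices the
embedding reproduces the reference implementation's qualitative behavior,
including its failure modes (cluster fragmentation and DBSCAN noise when
minPts = 50 meets small cohorts).

Two-round DBSCAN (ε 0.5, 50 points; then ε 0.2, 20 points, subclusters
nested by majority overlap) yields numeric cluster ids that are *not* stable
across runs or libraries, so labels are assigned semantically from
per-cluster medians: beta-positive clusters split into PPY-positive (III),
CD45-associated (II) and neither (I); beta-negative clusters into
PPY-dominant (IV) and glucagon-high (V), V splitting by CD45 association
(V-A vs V-BC). A cluster matching no rule is reported "unassigned", never
silently merged. The rule-based key applies the same decision list per islet
from three standard stains (INS, GCG, CD45; PPY optional), giving a
deterministic approximation for archival material; its truth table is in
`?rule_based_key`. The DBSCAN parameters were tuned upstream for a ~25,000
islet dataset: with a few hundred islets round 1 returns mostly noise
("null"), which is expected behavior, not an error — the pipeline then still
reports the rule-based key for every islet.

Summary tables apply the reporting suppression rule throughout: any cell
backed by fewer than 3 islets, or any group statistic represented by fewer
than 2 donors, is suppressed with a machine-readable reason.

## 5. Spatial statistics

The modified Ripley's K places circles of increasing radius (default 25
log-spaced radii, 400–10,000 µm; configurable upward to 20,000 µm) at each
islet, counts other islets inside, divides by the boundary weight — the
fraction of the circle area inside the tissue polygon — averages the
adjusted counts over islets, and normalizes by the expected count under
complete spatial randomness (slide density × circle area). K = 1 means
random; K = 2 means doubled local density. The quoted ordering
(weight-then-average) is the default; the pooled alternative (sum of counts
over summed expectations) is available behind `pooled = TRUE` for
sensitivity analysis. Islets whose weight falls below 0.01 at a radius are
skipped there to cap variance amplification. The circle–polygon intersection
area is computed exactly by a Green's-theorem decomposition (each polygon
edge contributes triangle or circular-sector terms) rather than the
64-gon-clipping approximation originally considered: the exact form is both
simpler to implement without a polygon-clipping library and eliminates the
documented <1% error; it is validated against a 10⁵-sample Monte-Carlo
oracle. One subtle case matters: a polygon edge exactly tangent to the
circle must contribute a sector, not a triangle, so the midpoint-inside test
is strict with a 10⁻¹² relative slack.

Fractal dimension is the OLS slope of log₁₀ mean boundary-adjusted count
against log₁₀ radius with radii ≤ 600 µm excluded; CSR patterns score ≈ 2,
collinear patterns ≈ 1.

"Delaunay clustering" is realized as a true Delaunay triangulation
(Bowyer–Watson, validated against a frozen `scipy.spatial.Delaunay` fixture)
with edges longer than 4,000 µm pruned. Mean Delaunay distance averages an
islet's retained incident edges; mean Delaunay area averages incident
triangles whose *three* edges are all retained (otherwise a pruned neighbor
could still influence the area). An islet with no retained neighbor receives
the fallback: distance 4 mm, area π·16 mm² (the 4 mm-radius circle). The
cluster-scoped variant triangulates each phenotype cluster separately with
an 8 mm radius; an islet with fewer than two same-cluster islets within 8 mm
is "isolated" (triangulation impossible for it).

## 6. The synthetic cohort generator

The generator is a stated world, not a tuning dial: its presets transcribe
printed group summaries, and free parameters were chosen once.

* **Stage templates** (`inst/extdata/templates/stage_templates.json`) carry,
  per stage × region: islet density, a truncated log-normal size law, the
  six-cluster mixture, subset fractions, a per-cluster CD45 model and
  per-cluster mean hormone fractions. Transcribed anchors include: IDI
  fractions rising from a few percent (Ctrl) through ~64% (T1DS PT) / ~84%
  (T1DS PH) to >99% (T1DL); GCG-deficient fractions ~34% (Ctrl PT) and ~56%
  (Ctrl PH), declining with progression; a ~10% PPY-dominant subset in the
  Ctrl PH growing to ~60% in T1DL; ≥1-CD45 prevalence ~25% (Ctrl) vs ~45–55%
  (AAb/T1DS); insulitis probabilities of ~0.6–0.8% (AAb) and ~1.3–3.2%
  (T1DS); control median diameters near 61–64 µm; islet densities of a few
  per mm², declining ~1.5–2× with progression.
* **Free parameters** (not printed upstream, chosen once as realistic):
  log-normal `sdlog ≈ 0.9–0.95` (reproduces ~80% of islets between 10³ and
  10⁴ µm²), negative-binomial CD45 counts (`mu = 2`, `size = 0.6`,
  heavy-tailed) with an insulitic component 15 + NB(10, 2), a 60% peri
  share, islet cell density 10,000/mm² (10 cells per 1,000 µm²) rising ~20%
  in clinical T1D, cluster size multipliers (II ≈ 1.9×, IV ≈ 0.47× matching
  a 44 µm median diameter), and a donor-level logit jitter of the cluster
  mixture with SD 0.15 — this last value is a guess, flagged as such, since
  within-donor dispersion is not printed.
* **Consistency constraints** are validated, not assumed: the cluster
  mixture sums to 1; the IDI fraction equals the beta-negative mixture mass;
  the marginal GCG-deficient fraction is decomposed into clusters that are
  deficient by construction (III, IV lack alpha cells), clusters that never
  are (V is glucagon-high), and a conditional probability inside clusters
  I/II that must land in [0, 1]; the ≥1-CD45 prevalence is *implied* by the
  per-cluster presence probabilities (`implied_cd45_prevalence()`), with
  CD45 concentrated in clusters II and V-A as observed.
* **Rendering**: islets are noisy star-convex polygons with controllable
  elongation, rescaled to exact target area, placed by rejection with a
  minimum 10 µm gap and strictly inside the tissue. Stain masks partition
  each islet's pixels into angular sectors per channel so that the union of
  the six defining channels tiles the islet exactly while each channel's
  pixel count matches its ground-truth fraction to rounding; CHGA is floored
  so the six defining fractions always sum to ≥ 1.05 (or CHGA = 1), which
  guarantees the tiling. Related channels share sector anchors (IAPP with
  INS, ProGCG with GCG) to produce realistic overlap.
* **Spatial thinning**: T1DS/T1DL templates remove islets from random disc
  patches (30% of area, 80% removal) to emulate stage-dependent density
  enrichment at short radii; the pre-thinning intensity is inflated so
  realized counts still match the configured density.

**What the generator does *not* emulate** — and hence what a green test does
not establish: brightfield image formation (stain intensity, background,
texture — inputs here are ideal binary masks), registration error between
staining rounds (masks are perfectly co-registered), segmentation artifacts
(dust, tissue damage; the upstream object classifier is out of scope),
exocrine nuclei outside peri-islet bands, lobular structure, and biological
correlation structures beyond those parameterized (e.g. islet-size–dependent
immune burden). Tests demonstrate that the pipeline recovers what the
generator put in; they cannot certify performance on real slides.

Two deliberate truncations keep configured probabilities exact: non-insulitic
CD45 counts are capped at 14 so the insulitic probability is exactly the
probability of crossing the ≥15 threshold, and the closed-form log-normal
median check applies only to templates with unit size multipliers and
negligible truncation mass (cohort presets shift cluster medians by design).

## 7. Determinism and reproducibility

Every stochastic stage takes an explicit integer seed; child seeds are
derived arithmetically (kept below 2³¹). RNG state is saved and restored
around seeded blocks, so library calls never perturb a caller's stream. The
UMAP optimizer is single-threaded with its own counter-based RNG. The
acceptance test re-runs the full synthetic pipeline twice and requires
byte-identical CSV/JSON artifacts.

## 8. Known limitations

* The UMAP/DBSCAN path needs on the order of 2,000+ islets before DBSCAN's
  minPts = 50 produces stable major clusters; small cohorts should rely on
  the rule-based key.
* Peri-islet geometry is raster-based (default 2 µm); areas converge at
  ~0.1% for 0.5 µm rasters but the polygonized outlines inherit pixelation.
* The Bowyer–Watson implementation is O(n²) per slide — ample for 10³–10⁴
  islets per section, not for whole-organ point sets.
* The rule-based key's thresholds are a declared reconstruction validated
  only against synthetic ground truth.
* Ripley variance envelopes (e.g. toroidal shifts) are out of scope.
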