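---
title: "Methods: human-interpretable image features and their models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: human-interpretable image features and their models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hifquant` turns dense tissue-type label rasters and classified cell tables
into a fixed catalog of 607 human-interpretable image features (HIFs), and
carries those features through feature clustering, association testing and
penalized prediction of binarized molecular phenotypes. This vignette is the
package's account of the underlying methods: the models and their
assumptions, the parameters that matter, the numerical choices, and what the
synthetic-data tests do and do not establish.

## Data model and geometry conventions

A slide is a pair (raster, cell table). The raster holds integer codes
0 = background/normal, 1 = cancer tissue (CT), 2 = cancer-associated stroma
(CAS), 3 = necrosis, at a stated resolution in microns per pixel (default
4 μm; cell coordinates are continuous microns at their native resolution).
Pixel `(r, c)` covers the half-open square `[(c-1)·mpp, c·mpp) ×
[(r-1)·mpp, r·mpp)` with the origin at the raster's top-left corner; a cell
belongs to a region if and only if its containing pixel does. This pixel
semantics makes region membership exact and side-steps boundary
double-counting.

Five analysis regions are derived per slide: CT, CAS, their union CT+CAS
(the tumor region), necrosis, and the cancer–stroma interface band (CSI).
The interface is the set of pixel edges shared by a 4-adjacent CT/CAS pixel
pair; the CSI band is every CT∪CAS pixel whose center lies within a
half-width (default 40 μm) of such an edge. The half-width is not fixed by
the published description of the interface-area feature; 40 μm was chosen
once so the full band spans 80 μm, matching the 80 μm radius used by all
proximity features, and is exposed in `hif_config(csi_halfwidth_um=)`.
Distances to the interface are computed with an exact Euclidean distance
transform on a 2×-resolution grid on which both pixel centers and edge
midpoints are lattice points, so the band is exact to the midpoint
discretization of the edges.

Connected components use eight-connectivity (a compiled flood fill);
*significant* components are those with at least 10% of the largest
component's pixel count, the largest always included.

## Morphometry

**Perimeter.** The estimator is the total length of the 0.5 iso-contour of
the component indicator, extracted by marching squares with subpixel linear
interpolation after smoothing the indicator with a Gaussian of σ = 1 px.
The smoothing is load-bearing: on the raw binary indicator the
marching-squares contour is a chamfered staircase that overestimates the
length of a digitized disk by ≈ 5.5% (worst case 8.2% for lines near 22.5°),
which would put perimeter²/area of a disk 11% above 4π. On the smoothed
field the contour tracks the underlying shape: measured errors are ≈ +1% on
a radius-500 px disk and ≈ −0.9% on rectangles (the four corners are
slightly rounded). The classic anchors — 16 for a square, 4π for a circle —
therefore hold to about 1%, which no unsmoothed local estimator achieves
simultaneously with rectangle accuracy. Components so small that the
smoothed field never crosses 0.5 fall back to the raw contour; a
single-pixel component returns its pixel-square perimeter 4·mpp by
convention.

**Fractal dimension** is the least-squares slope of log N(ε) against
log(1/ε) over dyadic box sizes 2…256 px, where N(ε) counts grid-aligned
boxes hitting the component's boundary pixels (or the interface edge
midpoints, for the CSI curve). Box sizes above half the set's extent are
dropped — including them flattens the slope for small components. Sets with
fewer than two usable sizes return the missing sentinel.

**Lacunarity** is the gliding-box statistic Λ(r) = E[M²]/E[M]² over all
r×r windows fully inside the raster, M being the in-window foreground mass,
computed with a summed-area table. The catalog fixes a single default scale
r = 32 px (configurable); a multi-scale spectrum would multiply the catalog
size without a printed total to anchor it. For per-component morphology the
box is capped at the component's bounding-box side so the metric stays
defined for small components.

**Other component metrics.** Axis lengths follow the equal-second-moment
ellipse convention (4·√eigenvalue of the pixel-center covariance, population
normalization), eccentricity is √(1 − λ₂/λ₁), the Euler number uses
bit-quad counting (8-connected objects, 4-connected holes), solidity is
pixel area over the convex hull area of the pixel squares, and filled area
fills 4-connected background regions that do not reach the bounding-box
border. Aggregation over significant components uses the population SD, so
a region with a single significant component reports SD 0 (no
heterogeneity) rather than a missing value.

## The 607-feature catalog

The published catalog states only category totals (13 area/multiplicity,
125 morphology, 25 architecture, 56 count/density, 208
proportion/proximity, 180 cluster; 163 tissue-derived, 444 cell-derived).
The per-feature decomposition inside each total is a pinned realization
chosen to reproduce those totals exactly, shipped as a manifest
(`hif_manifest()`) that names every feature with its category, cell class,
region, metric and scope:

* 125 = 10 metrics × 3 scopes {largest, significant-mean, significant-SD}
  × 4 regions + 5 CSI-largest metrics;
* 25 = {fractal dimension, solidity} × 3 × 4 + the interface fractal
  dimension;
* 56 = 5 classes × {count, density} × 5 regions + total count/density in
  CT, CAS, CT+CAS;
* 208 = 20 per-region class proportions + 80 ordered-pair 80 μm proximity
  counts/proportions (CT+CAS and CSI) + 15 cross-region density log-ratios
  + 15 interface-proximity class features + 40 unordered pairwise
  proportional counts + 38 interface-anchored contrasts;
* 180 = 9 cluster metrics × 5 classes × 4 regions.

The manifest invariants (607 total, the six category counts, the 163/444
split, unique ids) are asserted at build time; any configuration edit that
breaks a total is a hard error naming the category. Features undefined on a
slide (empty region, zero denominator, degenerate geometry) carry an
explicit `NA` sentinel — never a silent zero — and are imputed only after
Z-scoring.

Which regions host the pairwise proximity features is not pinned by the
published description; the manifest restricts ordered-pair proximity to the
tumor region and the CSI band, where cell–cell interaction hypotheses
concentrate, and flags the choice here.

## Birch cluster features

Per cell class and region, a CF (clustering feature) tree is built over the
cell coordinates in table order with subcluster radius threshold 100
(interpreted as microns, consistent with every other length in the catalog)
and branching factor 10, with no global reclustering step: the leaf
subclusters are the final clusters, their centroids the exemplars. Points
are then assigned to their nearest exemplar, which also defines cluster
sizes (summing to the number of clustered cells). "Within-cluster
dispersion" is fixed as the mean member–exemplar distance; extent is the
maximum. Ball–Hall is the mean over clusters of the mean squared
member–centroid distance; Calinski–Harabasz is the usual
between/within-variance ratio, undefined (NA) at K = 1 or N = K. Note that
with a 100 μm radius threshold, point sets spanning less than ~200 μm
typically collapse into one subcluster — two bundles must be separated by
several hundred microns before the tree splits them, which is the intended
scale for tissue-level hotspots.

## Synthetic scenes and cohorts

The generator replaces the upstream segmentation model with scenes whose
ground truth is known. Tissue geometry is a thresholded smoothed Gaussian
random field: background below the 0.55 field quantile, CAS to 0.75, CT
above, and necrosis above 0.97 — nesting necrotic holes inside tumor cores
and guaranteeing CT|CAS interfaces. Cells are homogeneous Poisson per
class × region at plausible tumor-microenvironment densities (fibroblasts
~1000/mm² in stroma, cancer cells ~2000/mm² in tumor, lymphocytes 300–800
/mm², sparse plasma cells and macrophages, a mostly acellular necrotic
compartment); lymphocytes default to a Thomas cluster process (parents 40
/mm², mean 15 offspring, 30 μm spread, truncated at the region boundary) so
cluster features have tunable, known structure. Cohorts add multi-site
structure (log-normal per-site and per-slide intensity multipliers,
SD 0.15/0.10), 1–2 slides per patient, and a phenotype
y = xᵀβ + ε built from the **re-extracted, Z-scored** features of the
generated slides: β is nonzero only inside randomly chosen HIF clusters and
scaled so the signal has unit variance; ε is Gaussian with SD 0.35, chosen
once so that a well-fit model reaches a hold-out AUROC near 0.9. Because
the phenotype is coupled to the extraction output rather than a stored
formula, any extraction defect breaks the downstream recovery tests.

What the generator does *not* emulate: stain and scanner variation,
segmentation error structure, anisotropic tissue textures, nucleus-level
morphology, or realistic inter-feature correlation beyond what the shared
geometry induces. Passing recovery tests therefore demonstrates the
correctness and statistical calibration of the pipeline, not performance on
real histology.

## Feature matrix, clustering, associations

Slides aggregate to patients by keeping the slide with the largest CT+CAS
area (ties to the smallest slide id). Z-scores use the population SD over
non-missing entries; constant columns map to 0; missing entries are imputed
as 0 (the cohort mean) *after* scaling, keeping the penalized models
defined. Z-scoring is idempotent on complete columns; imputed entries join
the cohort on a second pass, so the property is stated for complete data.

HIF clustering is complete-linkage agglomeration on 1 − |Spearman ρ|
(pairwise-complete, mid-rank ties; undefined correlations get distance 1)
cut at 0.95, so within every cluster all pairwise absolute correlations are
at least 0.05. Signature associations report per-HIF Spearman ρ with the
two-sided t-approximation on n − 2 df, per-cluster median |ρ|, the
Empirical Brown combination of the member p-values, and BH-corrected
q-values across clusters. Brown's transform uses the right-tail empirical
CDF with the (rank − 0.5)/n continuity convention (avoiding log 0), the
covariances are estimated from the member HIF values themselves (the
standard empirical formulation — the alternative of estimating dependence
from correlation statistics is not what the method's authors describe), and
input p-values are floored at 10⁻³⁰, the machine-precision floor. With all
covariances zero the combination reduces exactly to Fisher's method, which
the tests assert by construction.

## Prediction stack

Continuous outcomes are binarized at the root of
π₁N(x|μ₁,σ₁²) = π₂N(x|μ₂,σ₂²) between the component means of a
two-component unequal-variance Gaussian mixture (deterministic model-based
initialization; the root is solved in closed form as a quadratic and
clamped to [μ₁, μ₂]; a variance floor of 10⁻⁶·var guards EM degeneracies,
and an equal-variance fallback covers small-sample non-convergence).

Hold-out sets contain 20–30% of patients drawn entirely from tissue source
sites unseen in training: sites are shuffled by seed and greedily added,
skipping sites that would overshoot, warning and taking the closest
achievable fraction when the range is unreachable.

The logistic sparse group lasso minimizes mean deviance plus
λ[(1−α)Σ_g √p_g ‖β_g‖₂ + α‖β‖₁] with HIF clusters as groups. α is not
pinned by the published description; 0.95 follows the SGL authors'
convention and is configurable. The solver is proximal gradient with FISTA
momentum and a monotone safeguard, applying the exact SGL proximal operator
(elementwise soft-threshold, then groupwise shrinkage) each sweep; a group
is zeroed exactly when the soft-thresholded gradient fails the group-norm
test. A full-vector sweep was chosen over cycling through groups because it
vectorizes: it shares the objective and fixed points, the objective is
asserted non-increasing across sweeps, and it is what keeps nested
cross-validation at 300 × 607 tractable in R. Convergence is declared at a
maximum coefficient change below 10⁻⁶ (final refits; inner tuning fits use
10⁻⁴ and a 150-sweep cap, since their only job is to rank λ values by
AUROC). Path fits warm-start downward from λ_max — the largest per-group
root of the zero-coefficient condition — over a 30-point grid spanning
three decades, with sequential strong-rule screening verified against the
full KKT conditions so screened and unscreened paths coincide.

Nested cross-validation is stratified (3 outer, 5 inner folds; the
published description does not state stratification, adopted here for
small-n class balance; folds that lose a class are redrawn up to 10 times);
inner selection maximizes mean inner-fold AUROC with ties to the sparser λ
(the selection criterion — AUROC vs deviance — is not stated in the
published description; AUROC matches the reported evaluation metric).
The three outer models are ensembled by averaging predicted probabilities
and coefficient vectors. Evaluation reports AUROC via the Mann–Whitney
identity (mid-ranks), step-interpolated AUPRC, percentile bootstrap
intervals over 1000 paired resamples (single-class resamples redrawn), and
p = the bootstrap mass below 0.5, BH-corrected across a task battery.
Permutation inference re-runs the entire nested-CV ensemble per label
permutation and reports two-sided per-HIF p-values with add-one smoothing,
(1 + #{|β₀| ≥ |β|})/(B + 1), combined per cluster with Empirical Brown and
BH-corrected; whether the original fold assignments should be reused per
permutation is not stated, and fresh folds per permutation were chosen so
the null reflects the full training variability.

## Problem sizes and replication design of the shipped tests

The test suite exercises every stage at sizes a workstation handles in
minutes: scenes of 160 × 160 px at 4 μm (0.41 mm², a few hundred cells),
cohorts of 40–300 patients across 4–10 sites, B = 29–99 permutations, and
200-replicate calibration loops. The cluster-recovery benchmark extracts
one 300-patient cohort and then re-draws phenotype, site split and
cross-validation seeds across 20 replicates over the shared feature matrix
— replication over the stochastic stages whose behavior is under test —
rather than re-generating scenes per replicate, which would test the
(deterministic, separately tested) extraction twenty times over. Under the
null-calibration tests, permutation p-values are discrete with granularity
1/(B+1); the tests assert the floor, the non-inflation of the 0.05 tail,
and non-degeneracy of the null distribution rather than a narrow band on
one tail mass, which discreteness would make a coin flip.

## Known limitations

* The per-feature decompositions inside the published category totals are
  one consistent realization; other decompositions reproduce the same
  totals.
* The perimeter estimator trades exact rectangle lengths (−0.9%) for disk
  accuracy; both anchors hold to ~1%, neither exactly.
* Birch results depend on point insertion order (cell-table order), as is
  inherent to CF-trees; the order is deterministic per slide.
* The synthetic cohorts cannot certify performance on real histology (see
  above); they certify correctness, determinism and calibration.
* `cluster_hifs` materializes a 607 × 607 distance matrix — fine at this
  catalog size, not meant for catalogs orders of magnitude larger.
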