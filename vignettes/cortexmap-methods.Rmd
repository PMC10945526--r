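---
title: "Dense transcriptional cartography on cortical meshes: models and methods"
author: "cortexmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense transcriptional cartography on cortical meshes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexmap)
```

## The problem

Postmortem measurements of cortical gene expression are spatially sparse: a
few hundred microarray samples per donor, scattered over a cortical sheet
with roughly 20 mm between neighbouring samples. In vivo neuroimaging, by
contrast, delivers spatially dense maps at tens of thousands of surface
vertices. `cortexmap` builds the bridge: it imputes a dense expression map
(DEM) per gene on a triangulated cortical surface mesh, and provides the
statistical machinery that makes such maps usable — spatial-autocorrelation-
aware significance tests, transcriptional distinctiveness peaks, expression
gradient fields and their alignment with cortical folding, spatial
co-expression modules, and gene-set enrichment statistics.

Because the motivating datasets are large external resources, the package
ships a synthetic-cortex generator with planted ground truth. Every stage of
the pipeline is exercised, and its statistical claims calibrated, on
synthetic cortices whose generative parameters are known exactly.

## The DEM imputation model

For each donor and gene the pipeline is:

1. **Sample-to-vertex mapping.** Each tissue sample is assigned to the
   nearest unmasked mesh vertex by Euclidean distance; samples further than
   20 mm from any cortical vertex are excluded. Multiple samples on a vertex
   are averaged; ties go to the lowest vertex index.
2. **Nearest-neighbour interpolation** on the spherical projection: every
   vertex inherits the value of its nearest sampled vertex by great-circle
   distance.
3. **Geodesic Gaussian smoothing** with a 20 mm full width at half maximum
   (FWHM) kernel, `sigma = FWHM / (2 * sqrt(2 * log 2))`, truncated at
   3 sigma. The default FWHM matches the sampling density of the motivating
   data (about one sample per (18 mm)^2; the mean inter-sample distance is
   estimated as `d = 1 / sqrt(rho)` from the density `rho` in samples/mm^2).
4. **z-scoring across unmasked vertices** (population standard deviation).
   Donor effects that are affine in expression — per-donor scale and shift —
   are removed exactly by this step, which is why the synthetic donor model
   plants exactly that nuisance class and the tests assert its removal.
5. **Averaging across donors**, with Y-chromosome genes restricted to male
   donors.

Vertex-level z-scoring (rather than sample-level) avoids biases from
donor-specific sampling topographies. A gene with zero variance in a donor
contributes no map for that donor; the donor count per gene is recorded.

### Numerical choices in the smoother

The kernel weights `w(d) = exp(-d^2 / (2 sigma^2))` are applied to
area-weighted vertex values. Plain row normalisation preserves constants but
not the surface integral on irregular meshes; plain column normalisation
conserves the integral but not constants. We therefore balance the symmetric
kernel with a Sinkhorn-style diagonal rescaling so the operator is both
row-stochastic under area weights (constants are exact fixed points, to
1e-10 in the tests) and area-self-adjoint (the area-weighted mean of any
unmasked map is conserved to better than 1e-6 relative). Masked vertices
neither donate nor receive weight. The tests verify the impulse response
against an independently coded dense-kernel oracle.

### Geodesic distances

Geodesics are edge-weighted shortest paths on the mesh graph. A pure 1-ring
edge graph overestimates distances by up to ~20% in directions misaligned
with the mesh lattice, so the graph is augmented with 2-ring chord
shortcuts, which brings the worst-case error on an icosphere below 5% of the
analytic great-circle distance. This approximation is well inside the
tolerance set by the 20 mm smoothing scale at which all distances are
consumed.

### Tangential gradients

Per-vertex gradients come from a least-squares fit of an affine function
over the 1-ring neighbourhood, projected into the vertex tangent plane
(normal = area-weighted incident face normals; the first tangent axis is the
projection of global +x, falling back to +y near the poles of that choice).
The estimator is exact for affine fields on planar meshes and achieves
5-degree orientation accuracy at 95% of vertices for smooth spherical
harmonics on an icosphere-4 mesh. Gradients can be taken on the folded,
spherical, or flat representation; the default is the folded mesh.

## Spin tests

All map-to-map comparisons are tested against spherical-rotation
("spin") nulls: rotations drawn uniformly from SO(3), applied to the
spherical projection, with nearest-vertex reassignment. This preserves the
spatial autocorrelation of the spun map, which is what inflates naive
p-values. The p-value convention is `(1 + exceedances) / (1 + n_spins)`,
valid at finite spin counts; supported statistics are Pearson, Spearman,
Dice (binary pair), and delta-z (binary vs continuous). Orientation
*fields* are spun by parallel transport: the 3-D axial vector is carried
through the rotation and re-projected into the target vertex's tangent
plane. On a single hemisphere only pure rotations are used (no mirroring).

Calibration is asserted, not assumed: on 500 independent pairs of smoothed
Gaussian random fields (GRFs) whose autocorrelation matches the DEM
smoothing scale, the rejection rate at alpha = 0.05 must fall in
[0.03, 0.07].

Map-level family-wise error for vertex statistics (transcriptional
distinctiveness peaks, high-gradient regions) uses a maximum-statistic
construction: each gene's map is spun by an independently drawn rotation,
the vertex statistic is recomputed, and its maximum over vertices recorded;
the observed map is thresholded at the 95th percentile of those maxima. On
pure-noise libraries the any-suprathreshold rate is checked to sit at
5% +/- 3%.

A second, stricter null rebuilds entire DEM libraries after rotating each
donor's sample locations on the sphere before interpolation
(`spun_interpolated_null`), preserving each gene's sample-value multiset
exactly while destroying cortical localisation — this probes artefacts of
the interpolation itself.

## Transcriptional distinctiveness and peaks

`TD(v) = mean_g |z_g(v)|` indexes how extreme a vertex's expression profile
is across the whole library; for iid standard-normal maps it concentrates at
`E|N(0,1)| = sqrt(2/pi)`, an analytic limit the tests check to 0.02.
Suprathreshold vertices (max-statistic threshold, above) are clustered by
expression signature: pairwise Spearman correlation of gene ranks between
vertices, embedded by principal components retaining 95% of variance (a
minimum of two dimensions — a 1-D embedding of tight clusters makes
covariance estimation degenerate and over-splits), then a full-covariance
Gaussian mixture over a candidate range of component counts, selected by
BIC (ties favour fewer components). Peak gene sets take, at each peak's
maximum-TD vertex, the genes beyond the 95th centile of |z| in either
direction, so high and low lists may have different lengths.

## Gradient analyses and folding alignment

Per-gene gradient fields yield a mean-magnitude map (where expression
changes fastest) and, via the uncentred 2x2 second-moment tensor of gene
gradient vectors at each vertex, a principal orientation of expression
change with its explained-energy fraction. Orientation is axial (theta and
theta + 180 are the same axis), so tensors, not vector means, are averaged
throughout.

The fold-orientation field combines the gradient tensors of sulcal depth
and curvature (the former orients folds on sulcal walls, the latter at
fundi and crowns), smooths the tensor components with a 10 mm FWHM kernel
to propagate orientation into plateaus, and takes the leading eigenvector;
`lambda1 - lambda2` is the orientation magnitude and zero marks undefined
orientation. Alignment between two orientation fields is summarised by the
distribution of minimum axial angles (0–90 degrees): aligned fields pile up
near zero, giving positive Fisher–Pearson skewness, tested by spinning one
field relative to the other. Angles of independent fields are uniform on
[0, 90], whose skewness is zero — the type-I rate of the test is checked to
sit in [0.02, 0.08] at alpha = 0.05. Rather than globally flattening the
cortex with cuts, all angle comparisons happen in per-vertex tangent planes
with spun fields parallel-transported; on developable patches this agrees
with the flattening approach.

Region-of-interest (ROI) alignment works per parcel: PCA of member-vertex
coordinates projected into the parcel's mean tangent plane defines long and
short axes (near-circular parcels are flagged), and the field's
tensor-averaged orientation is compared to the short axis.

Candidate expression borders are ranked by each gene's mean gradient
magnitude over the border vertices; marker sets are scored by the fraction
of size-matched random gene sets achieving a median rank at least as good.
The columnar-profile boundary statistic (for segmented in-situ staining
intensity) scans all splits of the column sequence and returns the split
maximising the Welch two-sample |t| (Welch, because staining variance need
not be homogeneous; the t is signed, and a perfect step yields an infinite
t at the true boundary). The returned index is the first column of the
right-hand group.

## Spatial co-expression modules

The module pipeline follows the weighted co-expression network canon:
gene-gene Pearson correlation across vertices; signed soft-threshold
adjacency `a = ((1 + r)/2)^beta` with `beta` the smallest power whose
scale-free topology fit exceeds r^2 = 0.8 (fit = signed R^2 of log10 p(k)
against log10 k over ten equal-width connectivity bins; if no power reaches
the target the best-fitting power is used with a warning); topological
overlap `omega_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`;
average-linkage clustering of `1 - omega`; modules of at least 30 genes;
module eigenmaps as the first principal component of member maps across
vertices (sign-oriented so mean member correlation is positive, z-scored);
merging of module pairs whose eigenmaps correlate above 0.9; kME as the
gene-to-eigenmap correlation; and removal of modules significantly enriched
(Fisher, 0.05 divided by the module count) for a supplied set of
non-cortically-expressed genes.

One step required a design decision: the static dendrogram cut. A fixed
percentile of merge heights is unstable on libraries that mix coherent
modules with many unstructured genes — depending on the percentile it
either fragments modules or absorbs noise wholesale. We therefore scan the
candidate cut heights and score each partition by the sum, over clusters
reaching the minimum size, of cluster size times the excess of mean
within-cluster topological overlap over the global mean. The score drops
both when a module is fragmented and when weakly connected genes are
absorbed; the lowest height attaining the maximum is deterministic and
reproducible, and a fixed `cut_height` override remains available. On
libraries with five planted modules (100 genes each, loading 0.8, 500 noise
genes) this recovers the planted partition with adjusted Rand index above
0.99 and leaves noise genes unassigned.

## Enrichment statistics

Gene-set enrichment is one-sided hypergeometric (enrichment, not
depletion), with either Bonferroni-across-targets (the 0.05 threshold
divided by the number of target sets) or Holm–Šidák step-down control;
odds ratios get a Haldane 0.5 correction only when a zero cell would make
them undefined, and the correction is flagged. Protein-interaction
coherence of a module is the median intramodular degree against null
modules resampled within global-degree deciles matching the module's decile
profile. Developmental-trajectory coherence smooths each gene's expression
over log age (penalized spline, GCV), resamples 20 equally spaced log-age
points, z-normalises per gene, and compares the module's median pairwise
Pearson correlation to size-matched random sets. The annotation-similarity
network sets p-values above 0.1 to 1, weights edges by -log10 p, drops the
bottom decile of nodes by degree (edges at p < 0.05), and runs Louvain
community detection, keeping the best modularity over ten restarts.

## The synthetic cortex

Synthetic surfaces are subdivided icospheres (radius 100 mm; `10*4^s + 2`
vertices). Ground truth plants three gene classes:

- **module genes**: `loading * eigenpattern + sqrt(1 - loading^2) * noise`,
  where eigenpatterns and gene-level noise are smoothed, z-scored GRFs.
  `loading` is therefore the expected gene–eigenpattern correlation, which
  the tests verify by Monte Carlo.
- **boundary genes**: logistic steps across random great circles, with a
  configurable transition width in mm.
- **noise genes**: unsmoothed white noise, emulating transcripts without
  consistent cortical expression.

GRFs are used rather than spherical harmonics so the spatial scale is set
by a single FWHM knob that can match the DEM smoothing scale — which is
what makes the spin-test calibration honest. Donors measure the truth at
random vertex subsets under an affine donor distortion plus iid noise.
Default study conditions mirror the motivating data's geometry: six donors,
200 samples each, 20 mm smoothing.

Two scales matter and are deliberately distinct:

- For **spin calibration**, GRF pairs use the DEM smoothing scale (20 mm).
- For **end-to-end recovery**, the planted field scale must be resolvable
  by the sampling density. At 200 samples on an icosphere-3 the mean
  inter-sample distance is 25 mm, so truth fields at 20 mm FWHM are
  under-sampled and recovery saturates near r = 0.8 regardless of noise —
  an interpolation limit, not a pipeline defect. The recovery invariant
  (per-gene r >= 0.95 for noise-free donors) is asserted with 40 mm truth
  fields, above that limit.

What the generator does **not** emulate: realistic cortical geometry
(folding, medial wall shape), microarray probe-level noise, spatially
correlated measurement error, or donor-specific registration error. Passing
tests therefore demonstrate the correctness and calibration of the
algorithms under the stated generative model, not the biological fidelity
of any particular dataset.

## Problem sizes and determinism

The test-suite and acceptance-script simulations run on icosphere-2 (162
vertices) and icosphere-3 (642 vertices) meshes with 100–200 spin
ensembles, 50–200 permutations, and 150–500 Monte-Carlo repetitions per
calibration claim; these sizes give Monte-Carlo error comfortably inside
each asserted band. Every stochastic routine takes an explicit seed and
restores the caller's RNG state, so whole-pipeline runs are bit-for-bit
reproducible given a seed.

## Known limitations

- Graph geodesics (even 2-ring-augmented) are approximate; sub-millimetre
  distance fidelity is out of scope.
- Nearest-vertex spin reassignment can duplicate or drop vertices; at the
  mesh resolutions used the induced distance distortion is below one mean
  edge length, which the tests check.
- The GMM peak-count selection is only as stable as BIC on small vertex
  sets; below five suprathreshold vertices the peak set is returned
  unclustered with a warning.
- The scale-free fit target of r^2 > 0.8 is not always attainable on
  planted-module correlation structures; the warning path (best-fit power)
  is then taken deliberately.
- `fit_learning_curve` extrapolates a three-parameter saturating curve;
  with noisy inputs the asymptote is identifiable only to a few hundredths,
  as the tests quantify.
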