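---
title: "Biventricular shape-atlas analysis: models, parameters and design choices"
author: "bivatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biventricular shape-atlas analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bivatlas)
```

## The analysis in one paragraph

`bivatlas` quantifies regional biventricular remodeling in repaired
tetralogy of Fallot (rTOF) and asks whether statistical shape modes
discriminate patients referred for pulmonary valve replacement (PVR)
better than the standard global imaging indices. From corresponded
end-diastolic (ED) and end-systolic (ES) surface meshes it computes ten
imaging indices (BSA-indexed volumes and masses, ejection fractions and
the pulmonary-regurgitation measures), builds a PCA shape atlas after
generalized rigid alignment, selects a ten-mode feature subset by
chi-square ranking, fits confounder-adjusted linear models of every
feature against PVR status, clusters patients with cosine k-means on the
retained features (scored by the Matthews correlation coefficient, MCC),
and measures geometric systolic strain. A synthetic cohort generator
with analytic ground truth stands in for the CMR-derived meshes so that
every stage of the pipeline is testable end to end.

## The shape model

Each subject contributes a labelled triangulated surface with N vertices
in point correspondence across the cohort (LV endocardium, RV
endocardium, epicardium; four valve annulus rings). Stacked as 3N
coordinate vectors, the cohort is brought into a common frame by
generalized rigid alignment: every surface is aligned to the evolving
mean by the least-squares rotation + translation (Kabsch; no scaling and
no reflection), the mean is recomputed, and the loop stops when the mean
moves less than `tol = 1e-6` mm per vertex on average (at most 20
iterations; non-convergence is a warning, never silent). Scaling is
deliberately excluded: heart size is physiology, not nuisance, and body
size is handled downstream as a BSA covariate in the regression models.

PCA of the aligned, mean-centered vectors gives orthonormal modes with
eigenvalues in mm². With S subjects in general position there are
exactly S − 1 non-degenerate modes (eigenvalues above `1e-10` of the
leading one); `bv_atlas()` on an 84-subject cohort therefore returns 83
modes, and the acceptance script recomputes exactly this count. A
subject's Z-score on a mode is its projection divided by the mode's
population SD, so Z-score columns have unit sample SD over the training
cohort, and Z-scores are invariant to any rigid transform of the input
surface. Mode signs are fixed (largest-magnitude coordinate positive)
so results are reproducible run to run.

`bv_atlas()` is the package's central fitting function and behaves like
a classical R model object: `print()`, `summary()`, `plot()` (scree),
`coef()` (the Z-score matrix), `predict()` (project new surfaces),
`simulate()` (draw shapes from the Gaussian PCA model) and
`residuals()` (per-subject truncation RMS) are all available, with
`reconstruct_shape()` mapping Z-scores back to coordinates.

## Imaging indices

Cavity and wall volumes are computed by numerical integration of mesh
volumes: each labelled sub-surface is closed by capping every boundary
ring with a triangle fan to the ring centroid, and the closed surface is
integrated by signed tetrahedra (divergence theorem). The paper-level
definitions are: EF = 100·(EDV − ESV)/EDV; mass = wall volume × 1.05
g/mL (the standard myocardial density in the CMR literature; the source
study does not print a value); all volumes and masses indexed to BSA.
The wall is partitioned at the vertex level, with the septum assigned to
the LV wall — the same convention the strain analysis uses. The ten
indices (LV/RV EDVi, ESVi, EF, Mi, plus PRVi and PRF taken from the
subject record) deliberately match the size of the shape-mode feature
set.

## Mode subset selection and associations

Modes that cumulatively explain more than 95% of the shape variance are
candidates. Each candidate's Z-scores are discretized into 10 quantile
bins (bins with zero marginal count merged away) and a Pearson
chi-square test of bin × PVR-status gives an importance score
−log10(p); the top 10 modes by importance are retained. Quantile
binning and the deterministic tie-break (lower mode index) are
implementation choices; the binning count matters little for the
ranking order at n = 84.

Associations with PVR status use ordinary least squares on a normalized
response with PVR status, sex and repair type as reference-coded
categorical predictors (No-PVR, female, transannular patch) plus time
after repair — and, for shape modes only, BSA — as z-normalized
continuous predictors. Imaging indices are already BSA-indexed, hence
BSA is omitted there (an override is available). All continuous
variables including the response are z-normalized before fitting, so
the PVR coefficient is in standardized units and every reported p-value
is two-sided.

## Clustering and the matching matrix

Features significant at 0.05 are retained for clustering; when fewer
than two reach significance the next-lowest-p features are added so
each set keeps the minimum two variables. Patients are split into two
clusters by k-means under the cosine distance (1 − cosine similarity,
centroids renormalized each Lloyd step), which ignores absolute feature
sizes; 50 random restarts with a mandatory seed make the result
deterministic. Each cluster predicts the class of its dominant cohort;
ties resolve toward the higher MCC, then toward PVR; a single-class
prediction is flagged as degenerate. The MCC uses the standard formula
with a zero guard on vanishing marginals and equals the Pearson
correlation of the two binary indicator vectors. A threshold-criteria
comparator is also provided (RV EDVi > 160 mL/m², RV ESVi > 80 mL/m²,
RV EF and LV EF below configurable cutoffs — defaults 47% and 55% —
with two criteria required for asymptomatic and one for symptomatic
subjects); the EF cutoffs and count rules are configuration values
external to this package's estimation.

## Geometric strain

Longitudinal and circumferential strains are Cauchy strains,
100·(L_ES − L_ED)/L_ED, of arc lengths of structured parameter lines on
the endocardium: longitudinal lines run apex → basal ring along each
meridian, circumferential lines are the closed vertex rings, the septum
counts toward the LV, and lines are averaged unweighted. Radial strain
uses a centerline method on short-axis sections: planes normal to the
LV long axis (derived from the mesh, hence rigid-invariant) at 10–90%
of each ventricle's apex–base extent per phase (8 slices), endo and epi
contours extracted by plane–mesh intersection, stations paired by angle
about the shared contour centroid, the centerline taken as the
mid-curve, and wall thickness measured along chords normal to the
centerline at 100 stations. Chords that graze the contour (crossings
far outside the local radial wall) are rejected; slices a plane misses
are skipped and logged, and fewer than 4 valid slices is an error.
Station rays carry a half-step angular offset so they never run exactly
through mesh symmetry planes, which keeps the measure stable under
rigid transforms.

On analytic deformations the measures are exact: uniform scaling gives
LS = CS = RS = 100·(s − 1); in-plane scaling gives CS exactly; a
concentric-cylinder phantom with thickness 8 → 10 mm gives RS = +25%.
On curved meridians a pure long-axis scaling does *not* scale arc
lengths by the same factor — the package tests that case against dense
numerical integration of the continuous meridian rather than against
the naive factor.

## The synthetic cohort generator

The generator emulates the *statistical* structure of an 84-subject
rTOF cohort (48 PVR / 36 No-PVR), not its anatomy. Its components:

- **Template**: each ventricle is a truncated prolate ellipsoid
  endocardium with an offset epicardial shell truncated at the same
  base plane; the RV pair sits beside the LV pair, and the two
  epicardial shells are disjoint (the LV shell carries the
  septum-in-LV wall convention). Basal openings are split into two
  disjoint valve rings each by a flat bridge strip in the base plane,
  so all four annuli exist and capped volumes equal truncated-ellipsoid
  closed forms. Template dimensions are solved so that, at the
  reference BSA of 1.55 m², the indices sit at typical rTOF values
  (LV EDVi 79, RV EDVi 140 mL/m²; LV Mi 75, RV Mi 42 g/m²).
- **Planted modes**: five named deformation fields (RV apical dilation,
  RV basal bulge, LV dilation, LV conicity, pulmonary-annulus dilation)
  with unit peak displacement, mutually near-orthogonal (pairwise
  |cosine| < 0.2), with group-linked coefficient means (defaults ±0.6
  SD, conicity ±0.4; PVR positive on basal bulge, LV dilation/conicity
  and PV dilation, No-PVR positive on apical dilation). By default the
  fields are projected onto the volume-neutral subspace (first-order
  cavity/wall volume gradients removed), so group shape style is
  invisible to the global indices — precisely the phenomenon the
  shape-mode analysis exists to detect.
- **Background variation**: 40 orthonormal random smooth polynomial
  deformation fields (degree ≤ 3) with geometrically decaying SDs
  (50 mm leading, decay 0.96) give the long spectral tail real
  anatomies show; with the default settings roughly 25 modes are needed
  to pass the 95% variance cut, echoing the reference scree. Without
  this tail a handful of planted modes would explain nearly all
  variance, which no real cohort does.
- **Size**: geometry scales as (BSA/1.55)^(1/3); BSA comes from
  height and weight via Mosteller, drawn per group to match the
  published cohort characteristics, as are sex, repair type, times,
  pulmonary-regurgitation measures and the symptomatic flag (the
  asymptomatic proportion of the No-PVR group is not printed in the
  source tables; 80% is used).
- **ES frame**: a per-ventricle analytic contraction about the
  ventricle's own axis and base plane — longitudinal scale λ_L and
  endocardial circumferential scale λ_C drawn per subject from
  group-specific normals (means tuned to give RV EF ≈ 37% vs 42% and
  LV EF ≈ 46% vs 48%, SDs 0.035/0.05 giving EF SDs near 7 points) —
  with the epicardial circumferential scale solved per subject so wall
  volume is conserved exactly. EF ground truth is exact
  (100·(1 − λ_C²λ_L)), circumferential strain truth is exactly
  100·(λ_C − 1), and noise-free reference strains are available via
  `compute_true_strains()`.
- **Nuisance**: iid vertex noise (0.5 mm per coordinate) and a random
  rigid misalignment per subject (±10°, ±10 mm; shared by the
  subject's ED and ES frames, as a scanner pose would be).

Everything is reproducible bit for bit from `cohort_config(seed = …)`;
five named substreams (shape, noise, confounders, misalignment,
contraction) derive from the one seed.

What the generator does **not** emulate: real anatomy (no crescent RV
wrapped around the septum, no papillary muscles — the contour
convention excludes them anyway), spatially correlated segmentation
error, slice misregistration, valve-plane motion, or regional wall
motion abnormalities. Passing tests therefore certify the *analysis
machinery* — volumes, alignment, PCA, selection, inference, clustering,
strain — on data whose truth is known, not the clinical conclusions of
any particular cohort.

## Numerical choices

- Mesh resolution defaults to 14 rings × 28 meridians per component
  (≈1600 vertices); cavity volumes then sit within ~1.3% of the closed
  forms (the inscribed mesh underestimates; the error falls
  quadratically with resolution). Heavy simulation loops in the test
  suite use 8 × 16 meshes — resolution is a config parameter, and the
  statistical behaviour under study does not depend on it.
- Alignment tolerance 1e-6 mm (mean vertex displacement of the mean),
  eigenvalue degeneracy tolerance 1e-10 of the leading eigenvalue.
- Quantile binning uses type-7 quantiles; duplicate break points
  collapse (a constant mode gets importance 0 with a warning).
- The normality gate for group comparisons is Shapiro-Wilk at 0.05 per
  group; the t-test uses the pooled-variance form, the rank-sum test
  the midrank normal approximation without continuity correction.
- k-means: 50 restarts, empty clusters re-seeded at the farthest point,
  inertia compared with a 1e-12 slack so restart order cannot flip ties.

## Known limitations

- **Selection bias under the null.** The pipeline retains, by
  construction, the features most associated with the outcome (top-10
  modes by chi-square, then lowest-p retention with a minimum of two).
  With *no* group effect at all, the maximum spurious label correlation
  over ~25 candidate modes is still ≈0.25 in expectation, and the
  cosine 2-means split aligns with it, so null MCCs for the shape-mode
  set concentrate near 0.2–0.3 rather than 0. The acceptance suite
  quantifies this; it is a property of any label-driven retention rule,
  and a reason the discrimination results should be read
  comparatively (shape modes vs indices under the same selection), not
  as absolute performance.
- **Thin-wall radial strain.** RV wall thickness (~3 mm) is of the same
  order as a few multiples of the vertex noise, so per-subject RV
  radial strain is noise-amplified (thickness ratios); LS/CS, measured
  on long arcs, are far more stable. The phantom and noise-free checks
  bound the method error at <1%; the noise-driven spread is a property
  of the measurement, mirrored in practice by the known fragility of
  radial strain estimates.
- **Second-order volume effects.** Volume-neutralization of the planted
  fields is first-order; large excursions and the smooth background
  fields shift wall volumes by a few percent, visible as a ~2–3%
  downward bias of the cohort-mean mass index.
- The atlas is ED-only (as in the study design); no longitudinal
  trajectories and no supervised classifiers.

## Problem sizes used by the tests

The default test run builds one 84-subject cohort at full resolution
(shared across test files), uses 8 × 16 meshes for the 100-replicate
recovery and 100-seed null-clustering loops, 200 randomized instances
for the brute-force oracle comparisons, and 2000 null simulations for
the type-I-error check of the association model.
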