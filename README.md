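# bivatlas

Statistical shape-atlas analysis of biventricular cardiac geometry in
repaired tetralogy of Fallot (rTOF), asking whether regional shape
modes discriminate patients referred for pulmonary valve replacement
(PVR) better than the standard global imaging indices that currently
drive that referral.

The package is aimed at cardiac imaging researchers working with
corresponded surface meshes (LV endocardium, RV endocardium,
epicardium, four valve annuli) from CMR segmentations, and at
methodologists who want a fully synthetic, ground-truthed testbed for
atlas-based shape analysis.

## What it computes

Given per-subject ED/ES biventricular surfaces and a subject table:

1. **Imaging indices** — cavity volumes by numerical integration of
   mesh volumes, EF = 100·(EDV − ESV)/EDV, myocardial mass (wall
   volume × 1.05 g/mL), all indexed to BSA, plus PRVi and PRF:
   ten features.
2. **Shape atlas** — generalized rigid alignment (no scaling) followed
   by PCA of the stacked coordinates. For S subjects there are S − 1
   non-degenerate orthogonal modes; subject scores are reported as
   Z-scores *z*<sub>s,m</sub> = (x<sub>s</sub> − x̄)·φ<sub>m</sub> / σ<sub>m</sub>.
3. **Mode subset** — modes cumulatively explaining >95% of the
   variance, ranked by Pearson chi-square of quantile-binned Z-scores
   against PVR status; top 10 retained (matching the ten indices).
4. **Associations** — OLS of each normalized feature on PVR status
   with sex, repair type, time after repair (and BSA for shape modes)
   as confounders; features with PVR p < 0.05 (minimum two) retained.
5. **Discrimination** — cosine k-means into two clusters; the matching
   matrix against actual PVR status is scored by the Matthews
   correlation coefficient, MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN));
   repeated on the asymptomatic subset and compared with a
   threshold-criteria classifier (RV EDVi > 160 mL/m², RV ESVi > 80
   mL/m², EF cutoffs, symptom-dependent count).
6. **Geometric strain** — longitudinal/circumferential Cauchy strains
   from arc-length changes of structured parameter lines, and radial
   strain by a centerline method on short-axis plane sections
   (thickness along chords normal to the endo/epi mid-curve).

A synthetic cohort generator (`cohort_config()`, `generate_cohort()`)
emulates an 84-subject cohort (48 PVR / 36 No-PVR) with planted,
group-linked, volume-neutral shape modes, smooth anatomical background
variation, BSA allometry, rigid misalignment, vertex noise, and an
analytic wall-conserving systolic contraction — so every quantity above
has a known ground truth. See the methods vignette
(`vignettes/biventricular-shape-atlas.Rmd`) for models, parameters and
design decisions.

## Worked example

```r
library(bivatlas)
cohort <- generate_cohort(cohort_config(seed = 42))
report <- run_pipeline(cohort, stages = c("indices", "atlas",
                                          "associations", "clustering"))
print(report)
```

Output (abridged; exact numbers from this seed):

```
-- Imaging indices (PVR | No-PVR) --
  lv_edvi    77.5 +/-  6.3 |   77.1 +/-  4.7  p=0.691
  rv_edvi   136.3 +/- 11.6 |  138.8 +/-  8.6  p=0.146
  rv_ef      36.3 +/-  7.6 |   38.5 +/-  8.1  p=0.208
  ...

-- Shape atlas: 83 modes; 24 candidates under the cut; top 10 retained --
  selected modes: ED2, ED4, ED1, ED15, ED22, ED8, ED20, ED14, ED18, ED19

-- PVR associations (confounder-adjusted p) --
  prvi     0.003         | ED2    <0.001
  lv_esvi  0.277         | ED4    0.007
  ...
  retained: prvi, lv_esvi | ED2, ED4, ED8, ED1

-- Clustering discrimination (cosine k-means) --
  imaging_indices  MCC 0.00  sens 1.00  spec 0.00  [tp 48 fn 0 fp 36 tn 0]
  shape_modes      MCC 0.68  sens 0.77  spec 0.92  [tp 37 fn 11 fp 3 tn 33]
  threshold criteria   MCC 0.13  sens 0.92  spec 0.17
```

Reading this: the ten global indices barely separate the groups
(their clustering collapses to a single-class, MCC 0), while several
shape modes carry strong confounder-adjusted associations and their
cosine k-means clustering discriminates PVR status well (MCC 0.68,
specificity 0.92) — the planted regional remodeling is volume-neutral
by construction, so only the shape analysis can see it. `ED2` here is
the atlas mode aligned with the planted RV-apical/LV-dilation
contrast; `plot(report$atlas)` shows the scree, and
`render_mode_extremes()` writes ±2 SD meshes of any mode for
inspection.

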