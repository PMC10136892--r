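---
title: "PET-CT radiomics for checkpoint-inhibitor response: models, parameters and design choices"
author: "petrad authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PET-CT radiomics for checkpoint-inhibitor response: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrad)
```

## The analysis in one paragraph

`petrad` implements a complete radiomics pipeline for baseline
^18^F-FDG-PET-CT of advanced non-small-cell lung cancer patients starting
checkpoint-inhibitor (pembrolizumab-based) first-line therapy. The total
FDG-avid tumour burden is delineated with a PERCIST-style threshold
referenced to the liver, an 84-feature signature (shape, first-order
intensity, grey-level co-occurrence texture) is extracted per modality and
per reader, reader-unstable features are removed with Lin's concordance
correlation coefficient, predictive features are selected with a Boruta
shadow-feature random forest followed by correlation pruning, response is
modelled with logistic regression evaluated by ROC/AUC with Youden
cutpoints, and progression-free survival (PFS) is analysed with
Kaplan-Meier curves, log-rank tests and Cox proportional-hazards fits for
threshold-dichotomized features and TPS (PD-L1 tumour proportion score)
groups. Because the patient images behind the original analysis are not
public, the package ships a synthetic phantom-cohort generator with a
known ground truth; every stage is exercised and tested against it.

## Segmentation: the PERCIST-style threshold

The FDG-positivity threshold is

$$T = 1.5\,\mu_{liver} + 2\,\sigma_{liver},$$

with $\mu$ and $\sigma$ the mean and standard deviation of the SUV inside
a liver reference region. Choices the underlying definition leaves open,
and how this package fixes them:

* $\sigma_{liver}$ uses the sample ($n-1$) convention.
* The voxel inclusion rule is closed (`SUV >= T`), ties included.
* Connected components use 26-neighbourhood connectivity in 3-D;
  components smaller than `min_voxels = 2` are discarded as single-voxel
  noise.
* Manual reader adjustment (removal of physiological uptake in liver,
  heart, bladder) is modelled non-interactively as exclusion masks
  subtracted from the thresholded map.
* Any liver mask is accepted — a fixed-size VOI or a whole-organ contour —
  and its voxel count is recorded with the statistics.

## The 84-feature catalog

The published count is 36 first-order/shape plus 48 GLCM features per
modality, but no enumeration exists; the catalog here is a reconstruction
with IBSI-style definitions, fixed so the counts close and the named
features `PET-Skewness` and `PET-Median` exist:

* **12 shape features** (mask only): voxel count, volume, surface area,
  surface-to-volume ratio, two compactness variants, spherical
  disproportion, sphericity, maximum 3-D diameter, three principal-axis
  lengths. Surface area is computed from the boundary-face mesh — every
  voxel face exposed to background contributes its physical area. This
  estimator is exact for axis-aligned shapes (a 4 mm voxel reports
  96 mm^2) and converges to 1.5x the true area for smooth oblique
  surfaces, so sphericity saturates near 2/3 for large digital balls; the
  constant factor is irrelevant downstream because features enter
  rank-based selection and dichotomized analyses.
* **24 first-order features**: moments (population convention, kurtosis
  non-excess, skewness the Fisher-Pearson moment ratio), order statistics
  with linearly interpolated percentiles, energy/entropy/uniformity (the
  latter two on the discretized histogram), robust dispersion measures.
* **48 GLCM features**: 24 texture statistics at offset distances 1 and 2
  voxels. For each distance the symmetric, normalized co-occurrence
  matrices of the 13 unique 3-D directions are averaged into one matrix
  before statistics are computed, which makes the block invariant to
  90-degree rotations. Degenerate conventions: correlation and the
  information measures of correlation are 0 for a single-level region.

Grey levels come from equal-width discretization over the masked
intensity range with `bin_count = 64` by default (the source analysis is
silent on binning). Features are computed on the union of all lesions
(total tumour burden), not per lesion, and the count of 84 is per
modality — the PET and CT shape blocks coincide when both modalities share
one mask, which is flagged rather than hidden.

## Reliability, normalization, selection

* **Lin's CCC** with population denominators:
  $\rho_c = 2\,\mathrm{cov}(x,y)\,/\,(\sigma_x^2+\sigma_y^2+(\bar x-\bar y)^2)$.
  Features with $\rho_c \ge 0.8$ ("excellent") survive; kept features are
  merged as the arithmetic mean of the two readers.
* **Normalization**: z-score standardization composed with min-max
  rescaling to $[0,1]$ — the two published descriptions are individually
  inconsistent (z-scores are unbounded), and this composition is the
  package's resolution. Scaling parameters are fitted on training rows
  only and re-applied, never refitted, to test rows.
* **Split**: "balanced 70/30" is read as outcome-stratified;
  `round(0.7 n)` per stratum goes to training (33/11 becomes 31/13).
* **Boruta**: at each iteration the design is augmented with fresh
  permuted shadow copies of *all* original features (keeping the
  max-shadow bar at full strength even after most real features are
  rejected), a `ranger` random forest with impurity importance is
  fitted on the still-active features plus shadows, and hits against the
  maximum shadow importance drive two-sided binomial decisions at
  `alpha = 0.01`, Bonferroni-corrected across undecided features;
  leftovers are tentative and resolved by median importance against the
  median max-shadow importance. A caveat inherent to the algorithm: on a
  fixed small dataset, the luckiest noise feature carries persistent
  chance correlation with the outcome, which the iteration-wise binomial
  evidence model cannot distinguish from weak signal — so occasional
  false confirmations on null data are expected at small n and p, in
  this implementation and in reference implementations alike.
* **Correlation pruning** removes, within every pair with
  $|r| \ge 0.8$, the feature with lower Boruta median importance
  (deterministic order: importance descending, name ascending). Note the
  consequence: a cluster of near-interchangeable features is represented
  by its strongest member, which need not be the mechanistically "true"
  one — on phantoms, GLCM joint-average often measures the latent
  skewness trait better than the sample-skewness estimator itself and
  then represents that cluster.

Both endpoints — response at second follow-up (non-responder = PD) and
overall progression — run through selection and modelling independently.

## Response model and cutpoints

Per-feature univariate logistic models are the primary reported objects
(matching the per-feature AUCs in the source analysis); a multivariate
model on the pruned signature is fitted as well. The positive class is
the adverse outcome, so higher scores mean worse expected outcomes. AUC
is the tie-corrected Mann-Whitney estimator; the ROC uses the closed rule
`score >= t`. Youden's $J = \max(\text{sens}+\text{spec}-1)$ picks the
cutpoint, ties broken toward higher sensitivity and then lower threshold,
and the cutpoint is mapped back through the monotone logistic link onto
the normalized $[0,1]$ feature scale, where dichotomized survival
analyses operate. Logistic fits use IRLS; complete separation triggers a
flagged ridge fallback with escalating penalty. One published ambiguity —
fitting "on the test data set" — is resolved the only leak-free way:
fit on training data, evaluate on held-out data.

## Survival analysis

Kaplan-Meier estimation, Mantel-Cox log-rank and Cox
proportional-hazards fits are delegated to the `survival` package (Efron
tie handling — months-resolution PFS ties often; Wald 95% CIs). The
dichotomized analysis splits at the feature cutpoint and uses the
presumed low-risk side (low skewness, high median) as the Cox exposure,
so HR < 1 reads "protective", and reports 6-month survival per group from
the right-continuous KM step function. Stratified Cox is available via
the `strata` argument; the default analyses run unstratified because the
original strata are not named. TPS prognosis is assessed with per-level
Cox fits against the TPS < 1% reference.

## The phantom cohort: what it emulates, what it does not

`syntheticConfig()` fixes the study conditions:

| parameter | default | why |
|---|---|---|
| grid, spacing | 64 x 64 x 48 at 4 mm | PET-like resolution, desk-scale |
| liver SUV | Normal(2.0, 0.3) | typical liver reference; implies T = 3.6 |
| background SUV | 0.5 | soft-tissue background |
| lesions / patient | 1-3 ellipsoids, semi-axes 3-6 voxels | multi-lesion burden, >= 50 voxels each for stable texture |
| lesion median | U(5.5, 12) SUV | above T, FDG-avid range |
| lesion skewness | U(0.3, 2.2) | right-skewed uptake histograms |
| response link | logit P(non-resp) = -5.4 + 3.0 skew | ~25% non-responders; oriented AUC ~0.84 |
| PFS | Weibull(shape 1.3, scale 1.8), log-hazard 0.6 skew - 0.35 median | median PFS ~8-9 months, ~70-75% events |
| censoring | accrual horizon U(6, 30) months | staggered follow-up |
| TPS | multinomial (21, 13, 10)/44 | published cohort composition |
| reader 2 | 1 stochastic boundary edit | Dice ~0.97 |

Lesion voxels are drawn from a shifted-gamma family: the skewness target
fixes the gamma shape ($\gamma_1 = 2/\sqrt{k}$, closed form, which is
what makes oracle checks possible), the scale sets the spread, and the
shift pins the median exactly. Negative skewness targets mirror the
distribution around the median; the generator floors draws just above
the PERCIST threshold so planted lesions are exactly recoverable by
segmentation. Near-zero targets use the normal limit. The response link
was calibrated once, on latent traits at n = 8000, to sit in a
clear-signal regime (oriented AUC 0.8-0.9) — deliberately not at the
published 0.69/0.75, which are single-draw estimates from data that were
never deposited.

Reader 2's mask perturbation deserves a note: edits stay inside the
FDG-positive voxel universe (removing or restoring boundary voxels).
A naive whole-layer dilation would swap in pure-background voxels at
SUV ~0.5, which annihilates third-moment features in a way no real
reader of a threshold-defined mask would — with sharp phantom edges this
is an artefact of the phantom, not a property of readers.

What the phantom does **not** emulate: scanner point-spread blur and
partial-volume effects, respiratory motion, physiological uptakes other
than the liver, correlated CT morphology (the CT is smoothed noise with
no outcome signal, mirroring the null CT finding of the source
analysis), and any TPS-survival association (the configuration carries
no TPS coefficient). Passing tests therefore demonstrate the pipeline's
statistical machinery, not clinical performance on real images.

## Determinism and problem sizes

One master seed fans out to per-patient substreams (`seed + index`), so
cohorts are extensible without rewriting history; Boruta seeds each
iteration's forest, and a rerun of `runPipeline()` under the same
configuration is bit-identical. Simulation-based checks in the test
suite use desk-scale sizes chosen once: log-rank size at 1000 replicates
(n = 50/arm), Cox CI coverage at 500 replicates, the Boruta null at 50
runs (n = 200, 10 features), and full-image parameter recovery at
n = 96 patients across 8 seeds with a strong-effect configuration
(`beta_skew = 6`, `gamma_skew = 1.1`); the reproduction script uses a
n = 120 validation cohort. Degenerate inputs (empty masks, single-voxel
regions, constant features, single-class labels, thresholds at the
feature minimum) raise classed conditions rather than propagating NaN.

## Known limitations

* The 84-feature catalog is a reconstruction; other catalogs of the same
  cardinality exist.
* Face-mesh surface area biases sphericity-type features by a smooth
  constant factor (see above).
* The correlation-pruned signature names a cluster representative, not
  necessarily the generating feature.
* Small cohorts (n = 44 with 11 adverse events, test sets of 13) make
  test-set AUCs and Youden thresholds extremely noisy; the package
  reports them anyway, as the source analysis did, but stable estimates
  need larger synthetic cohorts.
* No DICOM ingestion, no acquisition physics, no overall-survival
  analysis, no contrast-CT radiomics — all out of scope.
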