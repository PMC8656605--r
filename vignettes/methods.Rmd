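---
title: "Automated prostate bpMRI assessment: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated prostate bpMRI assessment: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prostcad)
```

## Overview

`prostcad` implements an automated assessment pipeline for prostate
biparametric MRI (bpMRI: T2-weighted imaging plus diffusion-weighted
imaging, without contrast). The pipeline has three stages:

1. **Zonal segmentation.** T2WI is standardized geometrically and by
   intensity whitening, segmented slice-wise into peripheral zone (PZ),
   central gland (CG) and background by a pluggable backend, and the
   per-class probability volumes are reduced to a label map by per-voxel
   argmax.
2. **Lesion segmentation.** A computed high b-value DWI volume is
   derived from the acquired multi-b stack, channels are co-registered,
   geometrically standardized and intensity-normalized, a slice-wise
   backend produces a cancer-probability volume, and isotonic
   calibration, probability thresholding and minimum-size filtering turn
   it into clinically significant prostate cancer (CSPCa) lesion
   candidates.
3. **Reporting and evaluation.** Prostate lengths, zonal volumes, PSA
   density and per-lesion characteristics are derived and assembled into
   a structured JSON/HTML report; a separate evaluation suite computes
   segmentation, volumetric and lesion-level detection metrics with
   paired statistical comparisons.

The segmentation *network* is deliberately not part of the package. The
backend contract (`slice_predictor`) accepts any slice-wise model; the
package ships a ground-truth **oracle backend** whose accuracy is
controlled exactly (via `perturb_mask()`), so that every stage around
the network — which is where all of the package's computation lives —
is testable end to end without trained weights or patient data.

## The monoexponential DWI model

Diffusion signal at b-value $b$ is modelled per voxel as

$$ s(b) = s(0)\, e^{-b \cdot \mathrm{ADC}}, $$

with $s(0)$ the unattenuated signal and ADC the apparent diffusion
coefficient in mm²/s. `fit_monoexp()` estimates $(s_0^*, \mathrm{ADC}^*)$
by non-linear least squares under non-negativity bounds, initialized
from the log-linear ordinary least-squares fit of $\log s$ against $b$
(zero signals excluded) and refined by Gauss–Newton with step halving.
The log-linear initialization is exact on noiseless data, which is why
tests can demand recovery to below $10^{-9}$ mm²/s there. Voxels whose
signals all sit at or below a floor (default $10^{-6}$) short-circuit to
$(0, 0)$ so that air outside the patient never produces NaNs.

A computed high b-value image is then the extrapolation
$s(b_c) = s_0^* e^{-b_c \cdot \mathrm{ADC}^*}$, with $b_c = 2000$ s/mm²
by default — high b-value images have better lesion conspicuity, but
acquiring them directly costs SNR and time, so they are computed from
the low-b acquisitions ($b \le 1000$). For datasets that ship a
scanner-derived ADC map, `compute_high_b_from_adc()` provides the
alternative path $s(b_c) = s(b_{low}) e^{-(b_c-b_{low})\mathrm{ADC}}$
from the lowest-b image; which path is used is a pipeline choice, since
whether upstream ADC maps are refit or taken as supplied varies between
sites.

## Geometry and intensity conventions

All volumes use a fixed axis convention: x transverse, y
anterior–posterior, z cranio–caudal with z increasing towards the head.
Voxel centres sit at `origin + (index − 1) · spacing`; a voxel belongs
to a phantom ellipsoid iff its centre satisfies the ellipsoid
inequality. NIfTI files in other orientations are reoriented on read
from their header direction information.

Defaults for geometric standardization are an in-plane resolution of
0.4018 mm with a 320×320 in-plane crop for the zone pathway, and
256×256 centred on the prostate for the lesion pathway. Every geometric
operation returns a `geometry_record` so its inverse restores the
original shape exactly; only interpolated intensities differ, within
interpolation tolerance. Two conventions are pinned down explicitly so
tests can be exact:

* **Whitening** uses whole-volume mean and sample SD (not per-slice,
  not prostate-only) — the simplest reproducible choice where no
  restriction is inherent to the method.
* **Interquartile mean** (the CG-based intensity normalizer) computes
  quartiles by linear interpolation (`quantile` type 7) and includes
  values equal to either quartile. T2WI and computed DWI are divided by
  the interquartile mean of CG voxel intensities; ADC maps are *never*
  normalized, as they carry a quantitative measurement.

Registration of ADC/computed DWI onto T2WI is a pluggable provider with
the identity as default: production deployments delegate affine and
non-rigid registration to dedicated external tools, and re-implementing
those algorithms is out of scope here. The provider contract is
exercised in tests with a known-translation provider.

## Backend aggregation

Three aggregation mechanisms wrap any backend:

* **Ensembling** — per-voxel arithmetic mean across models.
* **Test-time augmentation (TTA)** — invertible 2D transforms
  (horizontal flip, ±10° rotation, ±10% isotropic scale — a fixed,
  reproducible discretization of typical training augmentation ranges);
  each transformed prediction is mapped back through the exact inverse
  and averaged with the plain prediction.
* **Test-time dropout (TTD)** — the mean over a configurable number of
  stochastic forward passes (default 10, seeded), with a default
  dropout probability of 0.2 for backends that support it.

When both TTA and TTD are active, a single pooled average is taken over
all passes and transforms; the alternatives (averaging TTA within each
dropout pass first) differ only in weighting and the pooled average is
the simplest order-invariant choice. Zone probability channels sum to 1
after every aggregation step because each mechanism is a convex
combination of probability maps.

Phantom evaluations run with TTA off and a single pass: the oracle
backend ignores its input, so transforming the input and
inverse-transforming the stored output would only corrupt it — TTA/TTD
are exercised by their own unit tests with stochastic toy predictors.
Phantom runs also use the phantom's native resolution and grid-sized
crops (`phantom_pipeline_config()`): the resample step becomes the
identity branch, keeping geometric closure exact so that the
perfect-oracle pipeline must reproduce ground truth voxel for voxel.

## Calibration, thresholding and size filtering

Raw cancer probabilities are calibrated by isotonic regression — the
non-decreasing least-squares fit computed by pool-adjacent-violators
(PAV) on voxel-level (score, in-CSPCa-lesion) pairs pooled over training
cases and subsampled per case for memory. Voxel-level fitting matches
how the calibrator is applied (voxelwise); the fitting granularity is
otherwise a free choice. The calibrator maps scores by linear
interpolation between fitted knots, constant beyond them.

A note on ROC invariance: calibration is *weakly* monotone. Wherever
PAV pools adjacent scores into one block, distinct raw scores collapse
to equal calibrated values, which can change the tie structure and
hence the ROC AUC slightly (towards the convexified ROC). When the
fitted rates increase strictly — no pooled blocks among the evaluated
scores — the map is strictly monotone and AUC is exactly invariant;
the test suite demonstrates both the exact case and the rank-ordering
guarantee (no inversions among distinct values) that holds always.

Candidates are the connected components (26-neighbourhood by default,
the most inclusive standard choice) of the voxels with calibrated
probability **≥** the cut-off C (default 4.5%); components with
physical volume strictly below 40 mm³ are removed. Both comparison
directions are pinned: a voxel exactly at C is positive, a component of
exactly 40 mm³ is kept. The 40 mm³ default is one fifth of the 200 mm³
guideline minimum for clinically significant lesions, allowing for
partially segmented lesions. The minimum size is interpreted as a 3D
volume (mm³): candidates are 3D objects, and the concrete operating
settings are stated volumetrically. Each candidate is scored by its
*maximum* calibrated voxel probability — consistent with reported
per-lesion probabilities reaching 100%, which a mean over the component
would rarely attain.

## Measurements and the report

* Prostate lengths are maximum extents of the whole-prostate mask
  (union of PZ and CG) per axis, with the voxel-footprint convention
  `(max − min + 1) · spacing`: a one-voxel object has its footprint as
  length, which is what "maximum extent" means at voxel resolution.
* Volumes are voxel count × voxel volume; PSA density is PSA divided by
  whole-prostate volume (ng/mL²).
* The base/midgland/apex assignment splits the whole-prostate z extent
  into thirds of equal *physical* length (robust to anisotropic slice
  spacing): the caudal third is the apex, the cranial third the base;
  boundary positions go to the midgland. The lesion centroid is the
  voxel-coordinate mean rounded to the nearest voxel; if that voxel is
  background (possible for a C-shaped PZ), the nearest in-prostate zone
  by physical distance is reported, a deterministic fallback. Centroid
  slices are displayed 1-based counting from the most caudal slice.
* `Min ADC` is the minimum ADC under the lesion contour; the
  extracapsular flag is set iff any lesion voxel lies outside the
  whole-prostate mask.
* The report lists candidates in descending probability (stable under
  ties) as LESION 1..n, and renders to canonical JSON (numeric fields
  rounded at build time: lengths/volumes 1 dp, PSA density 3 dp,
  probabilities whole percent, ADC 3 significant digits) so equal
  documents are byte-identical, plus a static four-section HTML view.
  The findings-summary wording is this package's own; only its field
  set is fixed.

## Evaluation suite

Segmentation is scored by Dice (two empty masks define Dice 1); lesion
segmentations additionally by Dice restricted to slices that contain a
ground-truth contour, since reference contours are typically drawn on
selected slices only. Volumes use absolute percentage error; PSA
density uses absolute error, because its absolute value carries
clinical meaning against decision thresholds. The ellipsoid formula
$l_1 l_2 l_3 \pi / 6$ is implemented as the clinical comparator.

Detection matching uses the **any-voxel-overlap** rule: a candidate
matches the ground-truth lesion of greatest overlap (ties to the larger
lesion); unmatched candidates are false positives; unmatched lesions
fall back to the maximum calibrated probability under their contour so
ROC analyses include missed lesions. Matching criteria vary across the
CAD literature and any-overlap is the most permissive standard choice;
it is configurable in principle via the outcome structure. False
positives are averaged over biopsy-negative patients only — in
biopsy-positive patients an unannotated detection cannot be proven
false. Specificity is computed over annotated non-significant lesions.

Paired statistics:

* **Wilcoxon signed-rank** (volumes, PSA density, FP counts): exact
  distribution for n ≤ 25 without ties, else normal approximation with
  tie and continuity corrections; zeros dropped.
* **McNemar** (sensitivity/specificity): exact two-sided binomial on
  the discordant counts; (0, 0) gives p = 1 by convention.
* **DeLong** (paired ROC AUCs): the structural-components covariance
  estimator, via `pROC`; equal AUCs short-circuit to p = 1.
* **Weighted generalized score test** (precision/PPV): each positive
  call contributes its lesion's true status; the score statistic for
  the rater effect is computed under the pooled null predictive value
  with a cluster-robust variance per lesion, so lesions called by both
  raters are not double-counted as independent. Its type-I error is
  verified by simulation.

## The phantom: what it does and does not emulate

`phantom_spec()`/`generate_phantom()` build nested-ellipsoid prostates
(whole prostate ⊃ central gland; PZ = WP − CG) with ellipsoidal lesions
of depressed ADC, T2 intensities per tissue, multi-b DWI generated
exactly from the monoexponential model (optionally with additive
zero-mean Gaussian noise clipped at zero), and full ground truth
including analytic volumes $\tfrac43\pi abc$ and diameters. Default
tissue values are plausible 3T magnitudes — PZ ADC 1.6×10⁻³, CG
1.3×10⁻³, lesion 0.8×10⁻³ mm²/s; b-values {0, 150, 500, 1000} s/mm² as
in multi-b prostate protocols — only the ordering lesion < tissue is
load-bearing. Gaussian rather than Rician noise is used deliberately:
it is the simplest model that exercises the non-linear fitter, and at
the SNRs tested the difference is immaterial to what the tests assert.

What passing phantom tests shows: the computation around the network —
signal modelling, geometry, normalization, aggregation, calibration,
candidate extraction, measurement, reporting, evaluation — is correct,
deterministic and internally consistent at controlled segmentation
accuracy. What it does not show: performance on real anatomy, real
noise, susceptibility artifacts, registration error or a real trained
network. Published external-validation figures of this kind of pipeline
(zonal Dice around 0.75–0.89, detection AUC around 0.70, a few false
positives per patient) require the original cohorts and trained
weights, which is precisely why the evaluation machinery here is
validated against analytic ground truth instead.

## Problem sizes and determinism

Phantom studies in the tests and the acceptance script use 48³×20 to
64²×24 grids at roughly 1 mm in-plane resolution, cohorts of 8–20
cases, a 0.5 mm isotropic phantom for volumetric convergence, 2000-
replicate null simulations for test sizes and a 10,000-replicate
bootstrap oracle for the DeLong check — sizes chosen so the full suite
exercises every closure property in a few minutes on one core while
keeping Monte-Carlo error well inside the asserted tolerances. Every
stochastic component (phantom noise, mask perturbation, dropout passes,
simulations) is seeded explicitly; identical seeds give bit-identical
results across processes.

## Known limitations

* DICOM series input is not implemented (NIfTI is the interchange
  format); DICOM writing and DICOM-SR are out of scope.
* The registration default is the identity: inputs are assumed
  co-registered unless an external provider is configured.
* The isotonic calibrator is fitted on pooled voxels, not per ensemble
  fold; per-fold calibration would require fold-resolved training
  outputs that a pluggable backend does not expose.
* The phantom's anatomy is deliberately schematic (nested ellipsoids,
  no bias field, no artifacts).
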