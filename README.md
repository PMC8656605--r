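# prostcad

Automated assessment and reporting of prostate biparametric MRI (bpMRI)
in R.

Radiologists reading prostate MRI must segment the gland, estimate its
volume (usually by the ellipsoid approximation), compute PSA density,
and identify lesions that may harbour clinically significant prostate
cancer (CSPCa, Gleason ≥ 3+4). `prostcad` implements the computational
pipeline that automates this read:

* **Computed high b-value DWI** — per-voxel non-linear least-squares
  fitting of the monoexponential diffusion model
  *s(b) = s(0)·exp(−b·ADC)* to the acquired low-b stack, extrapolated
  to *s(b_c)* at b_c = 2000 s/mm².
* **Zonal segmentation post-processing** — geometric standardization
  (common in-plane resolution 0.4018 mm, fixed crops), intensity
  whitening, ensemble/test-time-augmentation/test-time-dropout
  aggregation around a *pluggable* slice-wise segmentation backend, and
  per-voxel argmax into peripheral-zone / central-gland labels.
* **Lesion candidate extraction** — CG-interquartile-mean intensity
  normalization (ADC is never rescaled), isotonic (pool-adjacent-
  violators) probability calibration, thresholding at a cut-off
  C = 4.5 %, and removal of connected components smaller than 40 mm³.
* **Clinical measurements and report** — prostate lengths (maximum
  extents), zonal volumes (voxel counting), PSA density = PSA / volume,
  per-lesion centroid zone and base/midgland/apex region (thirds rule),
  minimum ADC, extracapsular flag; rendered as canonical JSON and
  static HTML.
* **Evaluation suite** — Dice, absolute (percentage) errors, lesion-
  level ROC/PR AUC, sensitivity/specificity/precision, false positives
  per biopsy-negative patient, and paired comparisons (Wilcoxon
  signed-rank, exact McNemar, DeLong, weighted generalized score test
  for predictive values).

The segmentation network itself is not reimplemented: any slice-wise
model can be plugged in behind the `slice_predictor` contract. For
testing, the package generates **synthetic ellipsoid phantoms** with
analytic ground truth and provides a ground-truth **oracle backend**
with exactly controlled Dice, so the entire pipeline is verifiable
without patient data or trained weights.

## Worked example

```r
library(prostcad)

case <- generate_phantom(phantom_spec(seed = 42))   # synthetic bpMRI case
res <- assess_case(case,
                   oracle_zone_builder(case, dice_target = 1),
                   oracle_lesion_builder(case, dice_target = 1),
                   config = phantom_pipeline_config(case))

m <- res$measurements
sprintf("WP volume: %.1f cm3 (analytic %.1f)", m$wp_volume_cm3,
        case$analytic$wp_volume_cm3)
#> "WP volume: 27.6 cm3 (analytic 27.6)"
sprintf("lengths: %.1f x %.1f x %.1f cm", m$transverse_cm,
        m$anterior_posterior_cm, m$cranio_caudal_cm)
#> "lengths: 4.0 x 3.0 x 4.5 cm"
res$report$sections$findings_summary
#> "The prostate measures 4.0 x 3.0 x 4.5 cm (transverse x
#>  anterior-posterior x cranio-caudal) with a volume of 27.6 cm3. PSA is
#>  8.00 ng/mL giving a PSA density of 0.289 ng/mL2. 1 clinically
#>  significant lesion candidate was detected; the most suspicious
#>  (LESION 1, probability 95%) lies in the midgland PZ with a volume of
#>  0.3 cm3 and a minimum ADC of 8e-04 mm2/s."
```

The whole-prostate volume (27.6 cm³) is the voxel count of the PZ∪CG
segmentation times voxel volume and matches the phantom's analytic
(4/3)πabc; the lengths are the mask's maximum extents; the single
candidate is the phantom's implanted low-ADC lesion, detected with the
oracle backend at Dice 1 and characterized from the label map and ADC
volume. `render_json(res$report)` and `render_html(res$report, path)`
write the full four-section report.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/prostcad.R phantom --out case1 --seed 7
Rscript inst/cli/prostcad.R cbdwi --dwi b0.nii,b150.nii,b500.nii,b1000.nii \
        --bvals 0,150,500,1000 --bc 2000 --out cb2000.nii
Rscript inst/cli/prostcad.R assess --out out1 --seed 7 --dice 0.9
```

## Package layout

```
R/               voxel grids + NIfTI I/O, phantom generator, DWI model,
                 preprocessing, backend aggregation, postprocessing,
                 measurements, report, evaluation, pipeline
tests/testthat/  unit, property and acceptance tests (all synthetic)
scripts/         acceptance.R
inst/cli/        command-line wrapper
vignettes/       methods vignette (models, conventions, design choices)
```
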