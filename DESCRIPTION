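Package: prostcad
Title: Automated Assessment and Reporting of Prostate Biparametric MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for automated assessment of prostate biparametric
    MRI (bpMRI). Provides computed high b-value diffusion-weighted imaging by
    per-voxel monoexponential model fitting, geometric and intensity
    preprocessing, a pluggable slice-wise segmentation backend with ensemble
    averaging, test-time augmentation and test-time dropout, zonal label-map
    post-processing, isotonic probability calibration with threshold and
    minimum-size filtering of clinically significant prostate cancer (CSPCa)
    lesion candidates, derived clinical measurements (prostate lengths,
    zonal volumes, PSA density, per-lesion characteristics), structured
    JSON/HTML report generation, and a lesion-level detection evaluation
    suite with paired statistical comparisons (Wilcoxon signed-rank,
    McNemar, DeLong, weighted generalized score). A deterministic synthetic
    phantom generator with analytic ground truth makes every stage testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    EBImage,
    igraph,
    jsonlite,
    pROC,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse
Config/testthat/edition: 3
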