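Package: ropzone
Title: Quantitative Measurement of Zone in Retinopathy of Prematurity from Ultra-Widefield OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the extent of retinal vascularization ("zone") in
    retinopathy of prematurity from segmented ultra-widefield OCT volumes.
    Extracts the retinal pigment epithelium surface from retina/choroid label
    volumes, connects manually annotated optic-disc, foveal and
    vascular-avascular border landmarks, measures retinal arclengths as
    geodesic distances along the RPE surface, and summarizes per-eye
    biomarkers: foveal distance, mean and minimum retinal arclength, the
    min-RAL to foveal-distance ratio, the assessed angle of the vascular
    border, a spherical-cap estimate of the area of vascularized retina, and
    a mathematical zone classification. Includes a synthetic infant-eye
    phantom generator with analytic ground truth and cohort-level statistics
    (AUROC with patient-cluster bootstrap confidence intervals, predictor
    comparisons, group differences, Pearson correlation).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph,
    RNifti,
    tiff
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
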