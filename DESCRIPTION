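Package: stereovol
Title: Cavalieri Stereology, Precision Prediction and Method-Agreement
    Simulation for Subcortical Volumetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design-based stereological volume estimation of 3D binary
    segmentation masks by the Cavalieri method with systematic uniform
    random point counting, prediction of the coefficient of error of a
    single estimate by the Gundersen-Jensen variance approximation, and
    the agreement statistics (two-way absolute-agreement intraclass
    correlation, hemispheric asymmetry indices, between-group ANOVA)
    used to validate automated volumetry against manual point counting.
    Includes a synthetic phantom-cohort generator (superellipsoid
    thalamus-scale shapes, two-group cohorts, noisy raters and an
    automated observer) so a whole volumetry validation study can be
    replicated in silico, plus NIfTI mask I/O for running the same
    pipeline on real segmentations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
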