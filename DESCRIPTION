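Package: laminarity
Title: Temporal Additivity Analysis for Laminar BOLD fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to test the linear-systems temporal-additivity assumption of
    BOLD fMRI as a function of cortical depth. Includes a forward simulator of
    laminar BOLD time series with a draining-vein signal model and optional
    nonlinearities, per-voxel signal conditioning (despiking, percent-signal
    scaling, polynomial detrending, temporal resampling), depth-quantile
    sampling of region-of-interest time courses, stimulus-locked epoch
    averaging with confidence intervals, shift-and-sum predictions of
    long-duration responses from short-duration responses evaluated by
    exhaustive split-half cross-validated Pearson correlation with a noise
    ceiling, and a depth-trend horizontality test. Reads and writes NIfTI
    volumes and plain-text design and result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
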