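Package: mriuq
Title: Conformalized Quantile Regression Uncertainty for Accelerated MRI Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixelwise uncertainty quantification for undersampled parallel MRI
    reconstructions via conformalized quantile regression. Provides a multi-coil
    Cartesian k-space simulator (ellipse phantoms, smooth coil sensitivities,
    complex Gaussian noise), autocalibrated Cartesian undersampling masks,
    zero-filled and mini-unrolled baseline reconstructions, sigmoid-scaled
    quantile-offset predictors trained with the pinball loss (or the
    residual-magnitude heuristic), conformal calibration of the offset scale
    with a Hoeffding-corrected miscoverage bound, and an evaluation suite of
    uncertainty/error maps, blurred Pearson and Spearman correlations,
    region-based correlation summaries, coverage, and threshold maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
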