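Package: brainagesim
Title: Simulation and Analysis of Age-Adjusted BrainAGE Associations
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Generative simulation framework for brain-age gap (BrainAGE)
    studies. Builds synthetic cohorts in which covariates and voxelwise
    gray-matter features arise from linear combinations of monotone-decreasing
    age basis functions, predicts age with a radial-kernel support vector
    regressor, computes BrainAGE (predicted minus chronological age) and its
    age-residualized form BrainAGER, and quantifies how adjusting for
    chronological age in downstream covariate regressions changes true and
    false positive rates. Includes closed-form results on regression toward
    the mean and the correlation between a response and its regression
    residuals, an FDR-based covariate screen for user-supplied tables, and a
    replicated experiment runner.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
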