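Package: usemr
Title: Effective Connectivity via Unified Structural Equation Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits unified structural equation models (uSEM) to multi-region
    time series, such as ROI-averaged fMRI signals. Each region is
    represented by its current and lag-1 series, so that directed
    contemporaneous and longitudinal (lagged) effects are estimated
    simultaneously by maximum likelihood on the pooled sample covariance.
    Includes a stationarity-checked generative simulator, ROI extraction
    from statistic maps and 4D volumes (cluster extent filtering, spherical
    masks), RMSEA-greedy stepwise model search with modification indices
    and parsimony pruning, descriptive fit indices (RMSEA, chi-square, TLI,
    GFI), and two-group comparisons through reversed-model cross-fits,
    hybrid models and per-path equality-constraint tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
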