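Package: beadprep
Title: Pre-Processing Benchmarks for Bead-Based Multiplex Immunoassay Data
Version: 0.1.0
Authors@R:
    person("beadprep", "maintainers", email = "maintainers@beadprep.invalid",
           role = c("aut", "cre"))
Description: Quality control, transformation and normalization of median
    fluorescence intensity (MFI) matrices from multiplex bead-based
    immunoassays (Luminex xMAP-style), together with a six-criterion
    scoring system to benchmark 37 combinations of six transformations
    (none, log2, asinh, Box-Cox, weighted Box-Cox, a variance-stabilizing
    transformation) and seven normalizations (loess, global median,
    quantile, dithered quantile, robust spline, z-score, vsn).
    Includes a synthetic-data generator emulating a reference-pool
    replicate design with heteroscedastic, right-skewed intensities,
    plate shifts and case/control group effects, so the whole benchmark
    runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
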