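Package: vesselfractal
Title: Scale-Resolved Fractal and Hurst Analysis of Stained Vascular
    Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the spatial organization of blood vessels in
    CD31/DAB-immunostained histology sections. Provides colour-gate
    vessel segmentation with morphological surface completion,
    fixed-grid box counting with a scale-resolved fractal dimension
    (the negative local log-log derivative of the box-count curve),
    Hurst-index estimation from the distribution of free-space lags
    between vessels, per-vessel perimeter-plane shape statistics, and
    whole-slide tiling with region-wise Mann-Whitney comparisons. A
    synthetic-histology module generates DAB-like tiles with exact
    ground-truth masks, ideal fractals of known dimension, and
    constructed gap patterns of known power-law exponent for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
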