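Package: landpatterns
Title: Multiscale Analysis of Landscape Pattern Change on Categorical
    Land-Cover Rasters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes six scale-invariant class-level landscape metrics
    (class area, number of patches, total edge, total core area, number of
    disjunct core area patches, and the Landscape Shape Index) on yearly
    categorical land-use/land-cover rasters tessellated into square
    landscapes at multiple extents.  Screens metrics for predictable
    power-law or linear scaling with landscape side length, and quantifies
    composition and configuration change per landscape between two years,
    including the nine-category cross-classification of class-area and
    shape-index change.  Ships a seeded neutral-landscape-model generator
    of ground-truthed synthetic land-cover time series so that the whole
    pipeline is testable without any external data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    parallel,
    pracma,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
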