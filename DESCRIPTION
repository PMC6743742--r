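Package: gridpop
Title: Harmonised Geospatial Covariates and Top-Down Dasymetric Population Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for building harmonised geographic covariate
    layers on a common mastergrid and disaggregating administrative census
    counts to grid cells. Implements snapped lat/lon mastergrids, polygon
    rasterisation, resampling and coastal no-data filling, exponential
    census interpolation with coarser-level growth-rate fallback, static and
    annual covariate derivation (spherical pixel areas, slope, land-cover
    reclassification, night-time-lights composites, cumulative protected-area
    series, built-settlement fusion, priority road rasterisation and highway
    intersections), random-forest dasymetric redistribution with exact
    per-unit conservation, population-at-risk and conflict-proximity
    summaries, and a seeded synthetic-world generator with known ground truth
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    ranger,
    deldir,
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    sp,
    withr
Config/testthat/edition: 3
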