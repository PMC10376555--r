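Package: mixrange
Title: Environmental Range Delineation and Overlap Statistics for
    Trawl-Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how multiple environmental factors (bottom
    temperature, salinity and depth) jointly constrain a fish
    population's spatial range from gridded trawl-survey data. The
    pipeline delineates the main biomass range (the region holding the
    top share of total biomass), interpolates biomass and factor fields
    by ordinary kriging with weighted-least-squares variogram fitting,
    decomposes the within-range distribution of each factor into normal
    mixture components by EM, maps the component intervals (mean plus or
    minus one standard deviation) back to spatial envelope masks, and
    computes point-count overlap statistics: effective ratio, coverage
    ratio, composite fitness index, and coverage declines under
    multi-factor intersections. A synthetic survey generator emulates a
    half-degree station lattice with seasonal temperature fields,
    river-plume salinity structure and offshore-deepening bathymetry so
    that every stage is testable without confidential survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
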