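Package: afforcast
Title: Process-Based Carbon Fixation Monitoring for Afforestation Stands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring carbon fixation in young afforestation
    stands by combining biometric field surveys with a simplified
    Biome-BGC-style daily process model. Reconstructs per-organ carbon
    density (aboveground woody, belowground woody, leaf) from harvest-tree
    allometry and tree-ring series; estimates daily vapour pressure deficit,
    shortwave radiation and daylength from station temperature and
    precipitation records; simulates stand carbon pools with Farquhar C3
    photosynthesis coupled to stomatal conductance, allocation, phenology,
    turnover, litter decomposition and a bucket water balance; calibrates
    ecophysiological parameters per monitoring phase by minimising a
    weighted relative-error objective with a derivative-free global
    optimizer (DIRECT, plus an evolutionary cross-check); and quantifies
    30-year carbon-fixation uncertainty by cyclic-climate ensemble
    projection. Seeded synthetic generators for weather, surveys and
    observation series make the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
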