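Package: senescreen
Title: Hit Calling and Phenotype Classification for High-Content
    Senescence RNAi Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Decision machinery for high-content siRNA screens that score
    cellular senescence. Implements control-anchored standard-deviation
    thresholds against per-plate scrambled controls, per-gene confidence
    ranking of library siRNAs, replicate-reproducibility ("2/3 wells in
    2/3 experiments") hit calls on senescence biomarker and cytokine
    panels, proliferation-class partitioning relative to seeding density,
    complete/partial/none senescence-response classification across an
    isogenic genotype panel, and a seed-anchored shortest-paths network
    stage with differential-expression overlay. A synthetic screen
    generator with the same statistical structure makes every stage
    testable without raw imaging data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
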