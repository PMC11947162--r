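Package: ferrospread
Title: Simulation and Quantification of Contact-Dependent Ferroptosis Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and quantify the spread of ferroptotic cell death
    through adherent cell monolayers. Provides a synthetic-data generator
    (hard-disc monolayer packing, cell-cell contact graphs, chain-binomial death
    propagation with optogenetic triggering and pharmacological modifiers,
    rendered multi-channel time-lapse image stacks, giant-unilamellar-vesicle
    oxidation-transfer traces, and lipidomics peak-area tables with known ground
    truth); image quantification (segmentation, background-corrected per-cell
    intensity timecourses, ratiometric C11-BODIPY oxidation scoring, DRAQ7-based
    death calling); spatial statistics on dead-cell point patterns (Hopkins
    cluster-tendency statistic, cross-population nearest-neighbour distances,
    permutation nulls); population death kinetics with percent-AUC summaries;
    lipidomics internal-standard normalisation and fold changes; and
    chain-binomial estimation of the per-contact spread probability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    yaml,
    tiff,
    deSolve,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
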