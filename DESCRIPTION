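Package: phenolms
Title: Untargeted HRMS Profiling of Cellular Phenolic Compounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Workflow for characterizing cellular phenolic compounds from
    direct-infusion negative-mode high-resolution mass spectrometry peak
    lists: signal-to-noise and relative-intensity filtering, blank
    subtraction, replicate consensus and fraction merging; constrained
    molecular-formula assignment from accurate mass; van Krevelen phenolic
    classification with the modified aromaticity index; molecular indices
    (elemental ratios, double-bond equivalents, nominal oxidation state of
    carbon) and Gini-Simpson abundance diversity; mass-difference
    transformation networks against a metabolite building-block table;
    four-parameter logistic EC50 dose-response fitting; and a
    synthetic-data generator with known ground truth for end-to-end
    validation of the workflow.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
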