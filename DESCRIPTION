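Package: ps6quant
Title: Quantification of pS6 Immunostaining and Behavioral Scheduling
    for Visual-Learning Experiments in Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring neural activation from pS6 (phosphorylated
    ribosomal protein S6) immunostained brain sections: blind randomized
    presentation of regions of interest, robust stained-area-fraction
    measurement of DAB-Ni stained tissue, per-region group statistics with an
    exact Mann-Whitney U test and log activation ratios, and the behavioral
    scheduling computations used in operant visual-learning experiments
    (constrained-random rotational schemes, session cycling, habituation
    schedules, learning-criterion detection). Includes a seeded synthetic
    histology generator with known ground-truth stain fractions for
    validation, and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
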