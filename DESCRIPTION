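Package: y1hscreen
Title: Interaction Calling for Arrayed Yeast One-Hybrid Colony Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores arrayed yeast one-hybrid (Y1H) selection screens run in
    1536-position quartet-replicated format. Reads Gitter-style colony
    quantification tables, applies quartet-level quality control (single-colony,
    low-area and dispersion filters on natural-log colony areas), builds each
    plate's background distribution with iterative Grubbs outlier screening and
    t-test based edge-effect correction, assigns one-sided Z-score p-values to
    every quartet, and calls bait-TF interactions that are significant at two or
    more 3AT selection levels. Includes a seeded synthetic-screen generator with
    planted interactions for end-to-end benchmarking, threshold-sensitivity
    curves, and per-species hit summaries with RNAi phenotype integration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
biocViews: Software, QualityControl, GeneRegulation, Transcription
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'calibration.R'
    'interactionCalling.R'
    'plateIO.R'
    'plateStats.R'
    'quartetQC.R'
    'screenIO.R'
    'screenReport.R'
    'syntheticScreen.R'
    'y1hscreen-package.R'
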