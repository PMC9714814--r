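Package: spatialCCI
Title: Spatial Code of Cell-Cell Interactions from Ligand-Receptor Coexpression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers a spatial code of cell-cell interactions from transcriptomic
    data and a curated ligand-receptor (LR) database. Builds binary communication
    scores by thresholding expression (>10 TPM), aggregates them into undirected
    cell-cell interaction (CCI) scores with a modified Bray-Curtis metric (plus
    LR-count, expression-product and permutation-based alternatives), derives
    minimum inter-nucleus distances between cell types from a 3D atlas, classifies
    them into short/mid/long ranges with a Gaussian mixture, and uses a genetic
    algorithm maximizing the absolute Spearman correlation between CCI scores and
    distances to select the LR subset that best encodes spatial organization.
    Includes Fisher-exact enrichment of LR usage by body section, distance range
    and ligand location type, permutation significance tests, a random-forest
    distance-range classification benchmark, and a synthetic-data generator with
    a planted spatial code for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    mclust,
    randomForest,
    pROC,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'lr-database.R'
    'expression.R'
    'communication.R'
    'cci-engine.R'
    'cci-scores.R'
    'spatial.R'
    'ga-selection.R'
    'stats-enrichment.R'
    'benchmark.R'
    'synthetic-data.R'
    'cli.R'
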