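Package: gridconflict
Title: Cognitive Conflict Assessment for Repertory Grids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing repertory grids from personal construct
    psychology: classification of bipolar constructs as congruent,
    discrepant, dilemmatic or neutral from self/ideal ratings; detection
    of implicative dilemmas via oriented Pearson correlations between
    construct rating rows; identification of prototypical figures;
    Gridcor-style summary indices (self-ideal discrepancy, self-perceived
    social isolation, perceived adequacy of others, polarization);
    pre/post intervention comparison along the two dilemma-resolution
    pathways; and a synthetic grid generator with planted conflict
    structure for method evaluation. Includes a plain-text grid file
    dialect, JSON result export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
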