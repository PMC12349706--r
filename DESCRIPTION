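Package: tetraco
Title: Tetrad Analysis of Meiotic Crossover Interference with a
    Two-Pathway Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for fluorescent-tagged-line (FTL) pollen tetrad analysis
    in Arabidopsis thaliana: classification of three-marker tetrads into the
    twelve observable phenotype classes, Perkins map distances, coefficient
    of coincidence and genetic interference with delta-method and bootstrap
    uncertainty, two-proportion and interference Z-tests, chiasma and
    bivalent-configuration statistics, binned foci-count summaries, and a
    forward simulator of two-pathway meiotic crossovers (an interfering
    Class I gamma-renewal process superposed on a non-interfering Class II
    Poisson process) that generates tetrad, metaphase-I bivalent and
    foci-count data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
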