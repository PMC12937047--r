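Package: haquant
Title: Double Isotopic Standard LC-MS/MS Quantification of Hyaluronic Acid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying endogenous hyaluronic acid (HA) in biological
    matrices by enzymatic depolymerization to tetrasaccharides and LC-MS/MS in
    multiple reaction monitoring (MRM) mode with two carbon-13 labeled internal
    standards. Provides exact-mass and molecular-formula arithmetic for
    HA-derived oligosaccharides, a generative model of the 13C isotopologue
    distribution of biosynthetically labeled oligomers (unit-level glucose
    labeling, acetyl-group heterogeneity, feedstock isotopic impurity) with
    closed-form parameter inversion, hypergeometric partitioning of residual
    12C atoms between precursor and product ions, MRM channel cross-talk
    checking, a seeded synthetic-data generator covering standard-addition,
    recovery/matrix-effect, robustness and freeze-thaw designs, chromatogram
    rendering and peak integration, and the full standard-addition
    quantification and bioanalytical validation calculus (LOD/LOQ, accuracy,
    precision, recovery, matrix effect, stability, robustness CV).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'formula.R'
    'isotopologue.R'
    'channels.R'
    'synthetic.R'
    'peaks.R'
    'quantify.R'
    'pipeline.R'
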