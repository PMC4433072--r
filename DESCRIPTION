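Package: pathreg
Title: Optimal Programs of Metabolic Pathway Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dynamic-optimization study of which enzymes in linear,
    converging and diverging Michaelis-Menten pathways are optimally
    placed under transcriptional control. Poses the enzyme-program
    optimal control problem (protein cost plus regulatory effort,
    product held in a band while its dilution changes), solves it by
    control vector parametrization with a multistart global search,
    and runs randomized-parameter ensembles scanning protein
    biosynthetic rate limits and product feedback inhibition
    strength. Also implements the promoter-length regulatory-effort
    statistics used to test the predictions on prokaryotic genome
    annotations (intergenic promoter proxies, sparse/pervasive
    pathway classification, positional and post-translational
    comparisons), together with a synthetic annotation generator
    with planted positional effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    rtracklayer,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
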