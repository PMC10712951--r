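Package: hippcat
Title: Hippocampal Circuit Simulations of Rapid Category Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rate-coded simulation of the hippocampal circuit (entorhinal
    cortex, dentate gyrus, CA3, CA1) trained as an autoencoder with
    theta-phase Contrastive Hebbian Learning. The trisynaptic pathway
    (EC to DG to CA3 to CA1) uses sparse connectivity and a fast learning
    rate, the monosynaptic pathway (EC to CA1) dense connectivity and a
    slow learning rate. The package generates three category-learning
    paradigms (feature-based satellite categories, the probabilistic
    Weather Prediction Task, and typicality-continuum categories),
    trains intact and pathway-lesioned networks, scores recognition,
    categorization and generalization behaviour, and computes
    representational similarity structure of the hidden layers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
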