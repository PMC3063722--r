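Package: mnemodel
Title: Maximum Noise Entropy Models of Binary Input/Output Computations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits maximum-noise-entropy (minimum-mutual-information) response
    functions for systems with binary outputs, such as neurons encoding
    sensory stimuli. Models of arbitrary interaction order are logistic
    functions of monomial input features fitted by moment matching
    (equivalently, maximum likelihood), and the information content of each
    set of moment constraints is quantified in bits. Includes exact Boolean
    logic-gate ensembles, an independent brute-force constrained
    maximum-entropy oracle, an end-to-end pipeline from spike trains and a
    stimulus trace to models in a reduced two-dimensional stimulus space,
    and a synthetic-data generator that plants known second-order models in
    naturalistic-like stimuli for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
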