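Package: falconfinch
Title: Falcon Finch Optimization and a Deep CNN Pipeline for Skin Lesion
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid swarm metaheuristic (falcon finch optimization) combining
    sparrow-search producer/scrounger foraging with Harris-hawk soft/hard
    besiege and a novel perching stage, for bound-constrained continuous
    minimization. The optimizer is embedded in a dermoscopy lesion
    classification pipeline: non-local-means preprocessing, eight statistical
    image features concatenated with a pluggable deep-feature backbone, a small
    convolutional network whose output layer is tuned by the optimizer, and
    k-fold / training-percentage evaluation harnesses reporting accuracy,
    sensitivity and specificity. A seeded generator of two-class synthetic
    dermoscopy-like images makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    png,
    jpeg
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
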