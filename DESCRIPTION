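Package: caviarid
Title: Forensic Species Identification and Mislabeling Surveys for Caviar
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Mitochondrial DNA barcode identification of caviar lots and
    survey-level mislabeling statistics. Implements a maximum-likelihood
    phylogenetic engine (GTR+Gamma site model, Felsenstein pruning,
    branch-length and shape optimization, sequence simulation along a
    tree, NNI tree search, bootstrap bipartition support), best-hit
    identity screening and phylogenetic placement of query sequences on a
    reference tree, a marker-escalation decision workflow
    (cytb -> D-loop -> cox1) with multi-egg confirmation and haplotype
    counting, exact binomial survey statistics, and a synthetic
    caviar-market generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phangorn,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Matrix
Config/testthat/edition: 3
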