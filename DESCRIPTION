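Package: evosig
Title: Signatures of Adaptive Evolution in Orthogroups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects lineage-specific signatures of adaptive evolution across
    a panel of species from orthogroup data: filtering of single-copy and
    fuzzy one-to-one orthogroups, detection of focal-species unique amino
    acid substitutions with an alignment-derived functional-impact score,
    flagging of genes with elevated root-to-tip divergence on per-orthogroup
    gene trees, and a branch-site codon-model likelihood-ratio test for
    positive selection on the focal branch with naive empirical Bayes
    identification of selected sites. Genes supported by at least two
    signatures are reported as showing multiple signs of adaptive evolution.
    Includes a seeded Gillespie codon-evolution simulator that generates
    orthogroup fixtures with planted signals and ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
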