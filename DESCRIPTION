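Package: tsnba
Title: Three-Step Network-Based Discovery of Disease Molecular Signatures and Key Regulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds perturbation-responsive disease molecular signatures and key
    transcriptional regulators from a protein-protein interaction network and
    condition-contrast expression data. Step one weights every interaction by a
    logistic function of the two endpoint log2 fold changes and ranks genes by
    total received interaction activity; step two filters the top-ranked genes
    through a Pearson co-expression network tuned to a target signature size;
    step three infers transcription-factor to target interactions with a
    correlation-based context likelihood of relatedness (CLR) procedure and
    screens key regulators with benchmark-overlap criteria. Five competing
    prioritization methods (fold change, degree, neighborhood scoring,
    interconnectivity, network propagation), a hypergeometric enrichment
    evaluation harness, and a seeded planted-signature simulator are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
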