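Package: cooccurnet
Title: Gene Similarity Networks from Co-Occurrence Probabilities of
    Categorical Mutation Attributes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the dissimilarity between genes from somatic
    point-mutation tables using a co-occurrence probability distance over
    categorical attributes (mutation type, nucleotide change).  For each
    gene and attribute an empirical conditional distribution is formed;
    the per-attribute distance is the maximum over category subsets of
    the paired conditional probabilities minus one, which reduces in
    closed form to the total-variation distance between the two
    conditional profiles.  Provides MAF and TSV readers, the all-pairs
    distance matrix, global/ego/intersection similarity networks with
    GEXF, GraphML and edge-list export, a synthetic mutation-table
    generator with known ground-truth distances, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
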