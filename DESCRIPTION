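Package: polyrekit
Title: Polyploidization-Rediploidization Inference from Synteny, Ks and
    Population Genomic Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and date ancient whole-genome multiplication
    events (duplications and triplications) and to characterise the
    rediploidization process that follows them. Includes homology filtering
    and collinear block chaining, Nei-Gojobori Ka/Ks estimation with
    Ks-peak mixture detection and strict-clock dating, LTR retrotransposon
    insertion-age dating, paralog retention-group classification,
    gene-tree based placement of polyploidy events on a species tree
    (MAPS-style subtree duplication percentages with null and positive
    simulations), exact conditional tests for expression divergence
    between retained duplicates, and copy-number-stratified selection
    inference (gamma distribution of fitness effects from the folded site
    frequency spectrum, adaptive divergence alpha and omega_a, fixation
    index). A genome-evolution simulator generates every input with known
    ground truth so each stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    mclust,
    jsonlite,
    yaml,
    pracma,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    rtracklayer,
    GenomicRanges,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
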