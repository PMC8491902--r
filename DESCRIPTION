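Package: ecaudit
Title: Annotation-Quality Audits for Enzyme Classes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing the quality of functional annotations within
    an enzyme class. Given protein sequences annotated to an EC number, a
    subset with experimental characterisation, and per-sequence domain
    architectures, the package quantifies each sequence's similarity to the
    characterised set using an alignment-free k-tuple prefilter followed by
    global alignment, clusters the class (Markov clustering or greedy
    identity clustering), selects informative representatives by Shannon
    entropy of cluster alignments, flags likely misannotations from identity
    thresholds and domain-architecture mismatches, compares annotation
    snapshots over time, and processes activity-screen and Michaelis-Menten
    kinetics data. A synthetic-data generator with known ground truth makes
    every stage testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
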