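Package: temine
Title: Mining Tc1/mariner Transposon Copies and Refining Majority-Rule
    Consensus Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An evolution-guided workflow for recovering all genomic copies
    of a Tc1/mariner DNA transposon, building a majority-rule consensus of
    the family, and annotating how that consensus differs from a reference
    element such as Sleeping Beauty. Provides a permissive built-in
    seed-and-extend homology search with PSL interoperability, a two-step
    "trim" search that accepts a transposase hit only when both inverted
    terminal repeats are detectable in its genomic flanks, reference-anchored
    multiple alignment with rule-based curation, per-column frequency
    profiling with a 60 percent inclusive consensus threshold, difference
    annotation with synonymous/nonsynonymous/frameshift classification,
    neighbor-joining phylogenetics with bootstrap support, and a synthetic
    genome simulator with full ground truth so every stage is verifiable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
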