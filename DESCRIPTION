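Package: mpabin
Title: Similarity-Based Taxonomic Binning of Metagenomic Reads via Most
    Probable Ancestors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns metagenomic reads to taxa from BLAST tabular hits and
    an NCBI-style taxonomy. Each read's assignment is first restricted to a
    taxonomic level determined by the alignment quality of its best hit;
    candidate ancestors are then enumerated by progressive lowest-common-
    ancestor computation over the score-ordered hit list, scored by summed
    bit-score to tree-distance ratios, and the read is assigned to the
    highest-scoring candidate (its most probable ancestor). A final
    reclassification pass promotes reads assigned to sparsely populated
    (isolated) taxa up the lineage instead of discarding them. Includes a
    plain lowest-common-ancestor baseline, accuracy/specificity evaluation
    against known read origins, and deterministic generators of toy
    taxonomies and synthetic hit tables for testing clade-deletion
    (unknown-organism) scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
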