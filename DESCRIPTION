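Package: paradiv
Title: Conservation Profiling and Expression-Pattern Divergence of Duplicated Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing duplicated (paralogous) developmental genes
    within and between species, built around the vertebrate Wnt gene family.
    Classifies columns of an outgroup-anchored protein alignment into
    paralogue-conservation categories and summarises conserved cysteines,
    paralogue-specific conservation and single-gene divergence; grades the
    spatial similarity of embryonic expression patterns between paralogue and
    orthologue pairs on an ordinal scale; and derives the shared-territory and
    reciprocity structure of a binary gene-by-territory presence matrix. A
    synthetic-data module generates alignments with planted column classes and
    expression annotation sets with planted similarity grades, so the whole
    pipeline can be exercised against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    rlang,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
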