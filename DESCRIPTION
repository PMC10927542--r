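Package: triumi
Title: Homotrimer UMI Error Correction and Molecular Counting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Error correction and deduplication for homotrimer unique
    molecular identifiers (UMIs), in which every base of a molecular tag is
    synthesized three times so that within-block disagreement reveals
    sequencing and PCR errors. Provides majority-vote trimer collapse with
    configurable handling of inconclusive blocks, per-gene set-cover
    deduplication (greedy solver with an exact branch-and-bound oracle), a
    Galton-Watson branching-process simulator of PCR amplification with
    negative-binomial error injection, read-structure utilities (anchor
    search, orientation, barcode whitelisting, gene tagging from SAM/BAM or
    TSV), spike-in CMI accuracy evaluation, and monomer-UMI baselines
    (first-base/random-base collapse, directional network deduplication).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    Rsamtools,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
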