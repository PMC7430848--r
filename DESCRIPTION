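Package: bandmap
Title: Long-Read Mapping by Anchor Credibility and Low-Column Banded Alignment
Version: 0.1.0
Authors@R:
    person("bandmap", "developers", email = "bandmap@example.org", role = c("aut", "cre"))
Description: Maps long, error-rich single-molecule sequencing reads (PacBio,
    Oxford Nanopore) to a reference genome. A fixed-length word index over the
    reference yields exact word matches for each read; a diagonal credibility
    score over the modified match positions selects one alignment starting
    position per read, and a reduced-memory (low-column) banded dynamic program
    extends the alignment from that anchor to both read ends, producing one
    end-to-end SAM record per read. Ships with a truth-emitting read simulator
    (substitution/insertion/deletion error model, structural-variant
    injection) and an evaluation suite: correctly-aligned read/base fractions,
    coverage ratios, base sensitivity/precision, inter-mapper agreement, and
    counting of reads that span structural-variant breakpoints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    methods,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
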