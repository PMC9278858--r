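Package: polterm
Title: Genome-Wide Analysis of RNA Polymerase III Transcription Termination
Version: 0.1.0
Authors@R:
    person("polterm", "developers", email = "polterm@example.org", role = c("aut", "cre"))
Description: Annotates RNA polymerase III terminators (T-tracts) genome-wide,
    calls read-through regions downstream of tRNA-like genes from
    strand-specific single-nucleotide nascent-transcription coverage,
    and computes termination statistics (read-through index and length,
    terminator-strength classes, condition fold changes, quartile group
    comparisons) contrasting a wild-type and a termination-deficient
    condition. Includes a stochastic polymerase elongation simulator that
    generates synthetic genomes and coverage tracks with known ground
    truth, so every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
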