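Package: lutiscan
Title: Discovery and Characterization of Long Undecoded Transcript Isoforms
Version: 0.1.0
Authors@R:
    person("LUTI", "Scan Developers", email = "lutiscan@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for detecting and characterizing long
    undecoded transcript isoforms (LUTIs): 5' extended mRNAs whose
    uORF-laden leaders translationally silence a downstream coding
    sequence while their transcription represses the canonical
    CDS-proximal promoter. Starting from 5'-end tag counts (TL-seq/CAGE
    style), long-read transcript spans, ribosome footprints, ChIP
    fold-enrichment tracks and MNase dyad coverage, the package performs
    distance-based TSS clustering, 5'-extended isoform discovery with
    long-read validation, uORF translation calling under a leaky-scanning
    model, promoter chromatin scoring, nucleosome positioning/fuzziness
    analysis, and a feature-correlation analysis of transcriptional
    repression. A fully synthetic study generator with planted ground
    truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
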