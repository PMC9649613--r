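Package: spliceRescue
Title: Downstream Alternative-Splicing Analysis for Splicing-Modulator Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream analysis of alternative-splicing (AS)
    quantifications produced by junction-count based differential splicing
    callers such as rMATS. Implements event-level coverage and significance
    filtering, cross-condition delta-PSI matrices with missing-data masking and
    k-means response clustering, splice-site k-mer enrichment against
    flanking-exon backgrounds, eCLIP peak based RNA-binding-protein enrichment
    (hypergeometric), quantification of drug-induced rescue of
    disease-associated splicing events, RPKM normalisation and
    transcript-consequence arithmetic for induced novel exons. Includes a
    truth-annotated synthetic-data generator emulating a four-condition
    splicing-modulator study so the whole pipeline can be exercised end to end
    without restricted-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
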