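Package: lincae
Title: Stacked Denoising Auto-Encoders for lincRNA Splice-Site Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects long intergenic non-coding RNA (lincRNA) transcription
    splice sites (acceptors and donors) in DNA sequence with a two-hidden-layer
    stacked denoising auto-encoder. DNA windows are converted to numeric
    vectors under five encoding schemes (DAX, EIIP, complementary,
    nearest-neighbour dinucleotide enthalpy, GF(4)); auto-encoder layers are
    greedily pretrained to reconstruct corrupted inputs and then fine-tuned
    for binary acceptor/donor classification. Includes confusion-matrix
    evaluation with seven metrics (sensitivity, specificity, accuracy,
    Matthews correlation, positive predictive value, performance coefficient,
    F1), FASTA/BED window extraction, a position-weight-matrix synthetic data
    generator, and a sliding-window scanner that nominates candidate sites.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
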