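Package: long16s
Title: Reconstruction of Near Full-Length 16S rRNA Genes from Dual-Tagged
    Illumina Amplicon Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing near full-length 16S rRNA gene sequences
    from paired-end Illumina reads of amplicons carrying dual 10-nt random
    molecular tags and 8-nt sample barcodes. Implements sample demultiplexing
    with phaser/barcode/tag/primer layout decoding, greedy clustering of dual
    molecular-tag signatures, elimination of in-vitro recombinants (PCR
    chimeras) by the dual-tag abundance rule, per-template read binning,
    quality trimming, k-mer error correction and de Bruijn contig assembly,
    map-back consensus calling with per-base PHRED qualities, amplification-
    bias estimation from cluster abundances, and a wet-lab protocol simulator
    with full ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
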