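Package: fqzip
Title: Lossless Reference-Based Compression of FASTQ Files
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lossless compression of FASTQ sequencing data against an external
    reference sequence. Records are split into metadata, nucleotide and
    quality-score streams; reads are mapped to the reference with a
    light-weight prefix-anchored k-mer model (reverse-complement fallback and
    segment re-mapping included), metadata are delta coded, quality strings
    are run-length-limited coded, and all intermediate streams are entropy
    coded with an adaptive bitwise context model driving a binary arithmetic
    coder. Decompression reproduces the input byte for byte, in the original
    read order. A deterministic synthetic-read generator is included for
    testing, together with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: C++17
Imports:
    Rcpp,
    Biostrings,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
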