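Package: genocodec
Title: Lossless Genomic Data Compression with Descriptor Streams and
    Context-Adaptive Arithmetic Coding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A modular, lossless compressor for sequencing data (FASTQ and
    SAM). Records are classified by alignment properties, regrouped into
    independently decodable access units, and encoded into integer
    descriptor subsequences using reference-based, local-assembly
    consensus, or verbatim low-latency strategies, with tokenized,
    delta-coded read identifiers and verbatim quality values. Descriptor
    subsequences pass through optional invertible transforms (equality,
    match, run-length), subsymbol splitting and a context-conditioned
    look-up-table transform, are binarized (binary, truncated unary,
    exponential Golomb) and compressed with a context-adaptive binary
    arithmetic coder. An exhaustive parameter optimizer selects transform
    and entropy configurations per descriptor subsequence, either globally
    or per access unit, under a 256-parameter-set container bound.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'genocodec-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'accessUnits.R'
    'catalogue.R'
    'compress.R'
    'container.R'
    'descriptors.R'
    'entropy.R'
    'fastq.R'
    'localAssembly.R'
    'optimizer.R'
    'records.R'
    'sam.R'
    'simulate.R'
    'tokens.R'
    'transforms.R'
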