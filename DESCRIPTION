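Package: kdtrim
Title: Quality-Aware Adapter Trimming via Bit-Masked k-Difference Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and removes adapter contamination from next-generation
    sequencing reads. The core is a bit-masked k-difference dynamic
    programming search with the Ukkonen cutoff that enumerates every
    adapter occurrence (and partial 3' overlap) within an error-ratio
    bound in expected O(kn) time and O(m) space, weighting mismatches by
    base-call quality on the -log10 probability scale. Single-end,
    paired-end (reverse-complement verified) and Nextera long-mate-pair
    junction trimming modes are provided, together with a read simulator
    producing ground-truth manifests, confusion-category benchmark metrics
    (PPV, sensitivity, specificity, Matthews correlation), ROC stringency
    sweeps, FASTQ input/output (plain or gzip, Phred+33/64) and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
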