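Package: tagcapture
Title: Tagmentation Capture Models and Chromatin Accessibility Peak-Set
    Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates Tn5 tagmentation on a synthetic genome with an
    accessible-chromatin landscape and converts insertion events into
    sequencing reads under two capture mechanisms: linear in vitro
    transcription capture of every insertion end (THS-seq style) and
    orientation- and spacing-constrained PCR capture of fragments between
    adjacent insertions (ATAC-seq style). Implements the downstream
    processing used to compare such libraries: clonal read removal, random
    down-sampling to a fixed unique-alignment depth, binned coverage, a
    transparent Poisson/Benjamini-Hochberg stand-in peak caller, base-pair
    and peak-level overlap statistics, length-stratified overlap with
    global normalization, three-way peak sharing, distances to
    transcription start sites, fraction of alignments in peaks, per-100-bp
    normalized peak counts with mean and standard error per peak-length
    bin, and the larger-30 percent versus smaller-70 percent capture-bias
    split.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    IRanges,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
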