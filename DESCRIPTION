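Package: micalite
Title: Seed-and-Extend Short-Read Alignment with Non-Branching Mismatch
    Seeding and Wavefront Affine-Gap Dynamic Programming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hardware-neutral short-read aligner library and command-line
    tool built around an FM-index over the reference genome. Seeds are
    searched by backward extension allowing one branching mismatch plus up
    to two non-branching (forced-correction) mismatches, over multiple
    rounds of decreasing seed length so that easy reads resolve early and
    only complicated reads reach the short-seed rounds. Candidate loci from
    the two ends of a read pair are paired under an insert-size model
    before verification, and surviving candidates are verified by an
    affine-gap dynamic-programming engine that fills the score table in
    anti-diagonal (wavefront) order over packed M/I/D cells, with soft
    clipping and CIGAR traceback. Includes a synthetic-data module
    (genomes, mutated donors, error-bearing paired reads with ground
    truth) and an evaluator reporting aligned, properly-paired,
    incorrectly-aligned counts, sensitivity and FDR, plus SAM output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    Rsamtools,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
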