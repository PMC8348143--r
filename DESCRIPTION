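Package: hmmpeaks
Title: Hidden Markov Model Peak Calling for Broad ChIP-seq Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide detection of enriched domains in ChIP-seq coverage
    with a three-state hidden Markov model (no-signal, background, peak) over
    fixed-width windows. Supports Gaussian emissions on mean window coverage
    (optionally log2-normalised against a control sample) and negative-binomial
    emissions on summed window counts, trained by Baum-Welch with a
    digamma-based iterative maximum-likelihood update for the negative-binomial
    dispersion. Includes Viterbi and posterior decoding, merging of adjacent
    peak windows into scored domains, BED and tab-separated output, a
    coverage-targeted ChIP-seq read simulator with ground-truth peak
    coordinates, and nucleotide-level interval metrics (Jaccard, true positive
    rate, false discovery rate, gene overlap) for benchmarking. Designed for
    long, weakly enriched histone-modification domains such as H3K27me3.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    GenomicAlignments,
    optparse,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
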