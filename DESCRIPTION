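Package: fastnr
Title: Silencer Detection in STARR-seq Data by Count Depletion and Curve
    Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies negative regulatory elements (silencers) from paired
    STARR-seq libraries by testing, at single-nucleotide resolution, for
    depletion of reporter cDNA coverage relative to the input insert DNA
    using the cumulative distribution function of the negative binomial
    distribution, extending significant nucleotides into fixed-width
    candidate windows, and filtering windows whose reporter and input
    coverage curves are too similar in shape (cosine, Euclidean, Pearson or
    gradient-correlation metrics). Includes a spike-in read-removal
    simulator that generates paired libraries with known silencers, plus
    benchmark statistics (detection power, call-set overlap, silencer
    strength, similarity-strength correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
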