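Package: pinvade
Title: Structural and Small-RNA Analysis of P-Element Invasions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring transposable-element invasions from pooled and
    individual short-read sequencing data, centred on the Drosophila P-element.
    Estimates copies per haploid genome by normalising element coverage to
    single-copy genes, detects internal deletions from split reads and estimates
    their population frequencies, classifies internally deleted variants as
    putative repressors from ORF defects and DNA-binding-domain integrity,
    computes piRNA ping-pong and phasing signatures and small-RNA length spectra,
    quantifies per-intron splicing from RNA-seq, applies full-length census rules
    to short-read samples and long-read assembly annotations, and simulates all
    required inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
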