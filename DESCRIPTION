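Package: palindromics
Title: Inversion-Symmetry Analysis of Transcription Factor Binding at
    Palindromic Response Elements
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the reverse-complement (inversion) symmetry
    of transcription factor binding at palindromic response elements such as
    the estrogen and ketosteroid hormone response elements. The package
    enumerates the Hamming-variant neighbourhood of a consensus palindrome,
    classifies variants into half-site groups by their reverse-complement
    vacancy structure, counts element occurrences in ChIP peak sets,
    converts counts to signal-to-noise ratios with one-tailed Poisson
    significance thresholds, quantifies the discrete binding-state plateaus
    implied by the pair-weight algebra, and tests single-strand k-mer parity
    (Chargaff's second parity rule) on genome sequences. A seeded simulator
    generates genomes, planted element variants and peak sets with known
    ground truth for end-to-end validation.
License: Artistic-2.0
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
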