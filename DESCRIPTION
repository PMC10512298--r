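Package: clonediv
Title: Micro-Divergence Analysis of Near-Identical Clonal Genome Assemblies
Version: 0.1.0
Authors@R: person("Genome", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to compare two or three near-identical haploid clonal
    genome assemblies, such as an ancestral fungal isolate and its
    laboratory-passaged derivatives. Provides flanking-consensus polishing
    of undetermined (N) regions in a draft assembly using two relative
    genomes, homopolymer-aware whole-genome identity metrics (gap-excluded
    and gap-compressed, with N masking), a syntenic gene-by-gene mutation
    caller with effect classification and polarization onto culture
    intervals, and a synthetic strain-trio generator with known ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
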