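Package: retroscout
Title: De Novo LTR Retrotransposon Discovery from Differential Small RNA
    and mRNA Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects candidate LTR retrotransposon loci from differential
    small-RNA and mRNA coverage between wild-type and RNAi-mutant samples,
    annotates them structurally (protein domain cassettes via position-specific
    scoring matrices, flanking direct repeats defining element borders,
    genome-wide copies and solo-LTRs via seeded banded local alignment),
    clusters elements into families at a 95% domain-identity threshold with
    neighbour-joining lineage assignment, profiles per-element small-RNA
    populations (size, strand bias, 5' nucleotide preference) to separate
    siRNA-like from sense-degradation-like species, and provides the
    relative-quantification arithmetic for qPCR expression, copy number and
    ChIP enrichment.  Ships a synthetic planted-element genome generator with
    ground truth for end-to-end evaluation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    ape,
    mclust,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
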