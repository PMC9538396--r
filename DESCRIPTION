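Package: solhex
Title: Detection, Dating and Subgenome Analysis of Ancient Hexaploidization Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-genomics toolkit for detecting and characterising
    ancient whole-genome triplication (paleohexaploidization) events from gene
    order and coding-sequence divergence. Provides collinear synteny-block
    chaining from all-vs-all protein homology hits, synonymous-substitution
    (Ks) estimation by Nei-Gojobori pathway counting, kernel-density plus
    Gaussian-mixture localisation of event-related Ks peaks, lineage-specific
    evolutionary-rate correction and absolute event dating, construction of
    hierarchical event-related multi-genome alignment tables, subgenome
    fractionation statistics (biased retention, geometric gene-loss run
    lengths, P-index allo/autopolyploidy diagnostic, shared-breakpoint
    two-step duplication inference) and gene-family expansion metrics. A
    fully-labelled synthetic hexaploid-genome simulator makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
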