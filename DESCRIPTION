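Package: domscan
Title: Domestication Scans, Diversity Statistics and SNP Array Design for
    Two-Population Genotype Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting artificial-selection (domestication)
    signatures from biallelic SNP genotypes in a wild-progenitor versus
    cultivated-crop panel: windowed nucleotide diversity, Tajima's D and
    Weir-Cockerham F_ST; a composite reduction-of-diversity (ROD) plus F_ST
    empirical-tail sweep scan with gene annotation; linkage-disequilibrium
    decay and half-decay distance; tag-SNP genotyping-array design;
    identity-by-state distances, principal components and neighbor-joining
    trees; multi-environment BLUP phenotypes and exact mixed-linear-model
    association with VanRaden kinship and a 1/n significance threshold. A
    forward Wright-Fisher two-population simulator with a domestication
    bottleneck, planted selective sweeps and multi-environment additive
    phenotypes makes the whole chain testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    ape,
    lme4,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
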