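Package: vmiap
Title: Mapping Trans-Acting Modifiers of Variably Methylated IAP Retroelements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting strain-specific trans-acting modifiers of
    variably methylated intracisternal A-particle (VM-IAP) retroelements in
    inbred mouse crosses. Provides a forward-genetic breeding and methylation
    simulator (Poisson-crossover meiosis with ancestry-painted chromosomes,
    locus-specific Beta methylation models, LTR sequence families with a
    planted discriminative motif, synthetic coverage tracks), per-locus
    methylation variability and phenotype classification, reciprocal-hybrid
    genetic-background-effect typing (Kruskal-Wallis with Dunn's post hoc
    test), backcross modifier mapping by phenotype-stratified SNP
    intersection, sequence-based target prediction (global alignment identity,
    progressive multiple alignment, discriminative-window scanning,
    cross-locus concordance, pooled t tests with two-stage
    Benjamini-Krieger-Yekutieli FDR), neighbor-joining LTR phylogenies with
    clade enrichment tests, and strand-aware anchored coverage metaprofiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape,
    phangorn
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
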