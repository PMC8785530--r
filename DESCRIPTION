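Package: domQTL
Title: Non-Additive QTL Mapping of Quantitative Lactation Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping dominance and recessive quantitative trait loci
    (QTL) in large crossbred dairy populations. Implements a two-step
    non-additive genome-wide association workflow: genome-wide additive and
    dominance SNP effects are sampled by BayesC0 Gibbs sampling and used to
    produce leave-one-segment-out (LOSO) adjusted phenotypes, after which
    genotype-class effects of dense test variants are sampled per posterior
    draw and summarised as additive (a), dominance (d) and standard-additive
    contrasts with z-statistics and Storey q-values. Includes additive +
    dominance GREML variance-component estimation from genomic relationship
    matrices, the marker quality-control filter cascades used for structure
    and sequence panels, iterative conditional scanning to separate co-locating
    QTL, and a synthetic mixed-breed genotype/phenotype simulator for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    Rcpp,
    data.table,
    vcfR,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'domQTL-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'simdata.R'
    'gqc.R'
    'greml.R'
    'adjust.R'
    'assoc.R'
    'itergwas.R'
    'pipeline.R'
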