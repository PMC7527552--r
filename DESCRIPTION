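Package: zanpop
Title: Population Genomic Inference for Chinese Pepper (Zanthoxylum)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-genomic analysis of genotyping-by-sequencing
    (GBS) SNP panels from Chinese pepper (Zanthoxylum bungeanum and
    Z. armatum) and similar non-model plants. Implements genotype matrix
    import and filtering, nucleotide diversity and Weir-Cockerham
    differentiation statistics, folded site-frequency spectra with
    hypergeometric projection, stairway-style effective-population-size
    trajectories, composite-likelihood fitting of multi-population
    coalescent demographic models with AIC comparison, f-statistics
    (f2/f3/f4/D) with block-jackknife errors, admixture-graph prediction,
    fitting and incremental search, and FST outlier scans (FLK and an
    Fdist-style simulation null). A structured-coalescent simulator
    generates synthetic genotype panels under explicit demographies so
    that every inference stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    ape,
    phangorn,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'zanpop-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'demography-class.R'
    'diversity.R'
    'simulate.R'
    'sfs.R'
    'models.R'
    'fitmodel.R'
    'fstats.R'
    'genotype-io.R'
    'graph.R'
    'outliers.R'
    'stairway.R'
    'pipeline.R'
    'utils.R'
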