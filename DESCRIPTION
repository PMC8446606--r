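Package: GenomicRRM
Title: Random Regression Models for Longitudinal Genomic Analysis of Crop Traits
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genomic analysis of longitudinal traits in inbred crop panels
    using random regression models (RRM). Builds Legendre orthogonal
    polynomial and B-spline covariance-function bases over a time axis
    (days after planting), computes VanRaden genomic relationship matrices
    from SNP dosages, estimates coefficient (co)variances by average
    information REML with heterogeneous residual classes, derives
    time-varying additive variance, heritability, genetic correlations and
    genomic breeding-value trajectories, performs k-fold cross-validated
    genomic prediction with accuracy and bias-slope summaries, and runs a
    longitudinal GWAS by back-solving time-dependent SNP effects from
    breeding values. Includes a synthetic recombinant-inbred-line data
    generator with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    vcfR,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'GenomicRRM-package.R'
    'crossValidation.R'
    'engineDense.R'
    'engineFast.R'
    'geneticParams.R'
    'grm.R'
    'gwas.R'
    'io.R'
    'modelData.R'
    'pipeline.R'
    'reml.R'
    'residualClasses.R'
    'simulate.R'
    'timeBasis.R'
    'utils.R'
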