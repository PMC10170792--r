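Package: wgsblup
Title: Genomic Prediction from Whole-Genome Sequence Marker Panels
Version: 0.1.0
Authors@R:
    person("wgsblup", "developers", email = "wgsblup@example.org",
           role = c("aut", "cre"))
Description: Tools for whole-genome-sequence genomic prediction of
    quantitative traits in livestock populations: marker-panel construction
    (call-rate/MAF quality control, random density thinning, sliding-window
    LD pruning, panel intersection), VanRaden genomic relationship matrices
    for SNP and INDEL sets, average-information REML estimation of variance
    components and heritability, GBLUP and MultiBLUP breeding-value
    prediction with cross-validated accuracy and bias, genotype-imputation
    accuracy metrics (concordance rate and dosage r2 by minor-allele
    frequency bin), and population-structure diagnostics (PCA, identity by
    state, LD decay, phenotype distance). Includes a synthetic-data
    generator emulating an admixed crossbred pig population so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    optparse,
    rlang,
    stats,
    utils,
    withr,
    yaml
Suggests:
    GenomicRanges,
    jsonlite,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
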