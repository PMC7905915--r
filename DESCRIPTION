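Package: estroPRS
Title: Polygenic Risk Scores from Estrogen-Metabolism Gene Variants in
    Breast Cancer Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A case-control association and risk-modelling toolkit for
    candidate-gene panels of estrogen-metabolizing enzyme and
    GWAS-identified breast cancer variants. Provides Hardy-Weinberg
    equilibrium quality control (goodness-of-fit chi-square and exact
    tests), per-genotype and per-allele odds ratios with Woolf confidence
    intervals, polygenic risk score construction from per-allele effect
    sizes with linkage-disequilibrium pruning, score-distribution
    comparison and ROC/AUC discrimination analysis, and OPLS-DA profiling
    of serum estrogen panels with VIP-based biomarker selection. Includes
    a synthetic cohort generator that draws genotypes under
    Hardy-Weinberg equilibrium at specified control allele frequencies
    and per-allele odds ratios, and log-normal estrogen panels with
    group fold-changes, so every pipeline stage can be exercised and
    calibrated without individual-level study data. Bundles the published
    genotype count tables for a 15-SNP estrogen-metabolism panel
    (140 cases, 140 controls) as a worked reference dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    yaml,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SNP, GenomeWideAssociation, Metabolomics, Classification,
    StatisticalMethod
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cohort-io.R'
    'association.R'
    'estroPRS-package.R'
    'estrogen-profile.R'
    'prs.R'
    'evaluation.R'
    'genotype-qc.R'
    'simulate.R'
    'pipeline.R'
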