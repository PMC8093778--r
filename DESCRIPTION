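Package: imgtx
Title: Imaging Transcriptomics of Regional Homogeneity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Links regional homogeneity (ReHo) of spontaneous brain activity,
    measured as Kendall's coefficient of concordance over voxel
    neighbourhoods in resting-state BOLD fMRI, to spatial gene expression.
    Provides voxel-wise ReHo mapping with z-standardisation, smoothing and
    atlas aggregation; Allen-Human-Brain-Atlas-style expression preprocessing
    (intensity filtering, probe selection, sample-to-region assignment,
    scaled robust sigmoid normalisation); weighted coexpression module
    detection (soft-threshold adjacency, topological overlap, dynamic tree
    cut, module eigengenes); spatial module-phenotype association with
    Bonferroni correction and a multi-dataset replication rule; cell-type
    specificity indices with permutation p-values and Fisher overlap tests;
    and competitive gene-set analysis of GWAS summary statistics with an
    LD-aware gene model. A synthetic-data layer with planted ground truth
    makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    IRanges,
    S4Vectors,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'association.R'
    'celltype.R'
    'expression.R'
    'gwas.R'
    'imgtx-package.R'
    'io.R'
    'modules.R'
    'pipeline.R'
    'reho.R'
    'synthetic.R'
    'utils.R'
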