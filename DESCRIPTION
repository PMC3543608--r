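Package: hlaSupertype
Title: Consensus Supertype Classification of HLA Class II Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for grouping HLA class II alleles (DR, DQ, DP) into
    supertypes from two complementary views of their peptide-binding
    behaviour: measured IC50 binding repertoires, binarized under
    quantile or fixed-threshold rules, and 15-residue structural binding
    motifs read off beta-chain contact positions in HLA-peptide complex
    structures. Cluster support is assessed with multiscale bootstrap
    resampling and approximately unbiased (AU) p-values with standard
    errors; significant clusters are extracted by iteratively relaxing
    the AU cutoff and intersected across the two views to give consensus
    supertypes. The package also computes peptide binding-promiscuity
    statistics (cross-locus versus locus-exclusive binding), labels
    peptides by percentage of positive activity (PPA), and benchmarks
    binder/non-binder classifiers (SVM, random forest, naive Bayes,
    neural network, k-NN) under random subsampling and leave-one-out
    cross-validation. A seeded synthetic-data generator with exported
    ground truth makes every stage runnable and testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    ape,
    bio3d,
    e1071,
    randomForest,
    nnet,
    class,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
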