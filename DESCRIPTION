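Package: geoancestry
Title: Biogeographic Ancestry Panels, Classification and Likelihood Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building biogeographic-ancestry platforms from
    genome-wide SNP genotypes: quality control and relatedness filtering of
    dosage matrices, principal-component analysis with iterative outlier
    removal, K-means grouping of populations into size-bounded ancestry
    groups validated by Hudson FST, selection of compact ancestry-informative
    marker panels by per-class chi-square prefiltering and randomized-tree
    stability selection, a probability-emitting one-vs-rest logistic
    ancestry classifier, and inverse-distance-weighted geographic surfaces
    of ancestral-origin likelihood. Includes a hierarchical Balding-Nichols
    genotype simulator with planted ancestry-informative markers for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    data.table,
    ranger,
    glmnet,
    geosphere,
    vcfR,
    png
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
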