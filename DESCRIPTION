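Package: netresect
Title: Virtual Resection of Structural Brain Networks and Outcome Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the predicted post-operative structural connectome from
    pre-operative tractography and a resection mask by deleting every
    streamline that intersects the mask, quantifies the induced network
    change with weighted graph measures (strength, betweenness centrality,
    clustering, communicability, global efficiency), and relates
    connection-change features to binary surgical outcome via elastic-net
    regularised logistic feature selection followed by a class-weighted
    linear support vector machine under leave-one-out cross-validation.
    Includes digital-phantom generators (parcellations, streamline bundles,
    resection masks, outcome-labelled cohorts) so that every pipeline stage
    can be exercised without imaging data, plus the group-comparison
    statistics used in cohort tables (permutation tests on means, Pearson
    chi-squared, Kruskal-Wallis).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    Matrix,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
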