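Package: dgclust
Title: Dynamic Graph Clustering Learning for Unsupervised Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Unsupervised deep clustering of images by dynamic graph clustering
    learning (DGCL): a small convolutional encoder produces Euclidean-level
    features, a k-nearest-neighbour graph and a two-layer graph convolution
    produce topological features, and the two are fused into one representation.
    Training is driven by two dynamic memory stores that evolve online with the
    network: a sample memory of unit-norm fused features with pseudo-labels
    (momentum-mixed each step) and a centroid memory refreshed on a schedule,
    with nearest-centroid relabelling and inverse-cluster-size class weights.
    Includes a synthetic image generator with planted cluster structure,
    preprocessing and augmentation for fundus-style photographs, a fuzzy
    c-means variant, and clustering/classification metrics (Hungarian-matched
    accuracy, NMI, ARI, sensitivity, specificity, ROC-AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    png,
    jpeg,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    mclust,
    pROC,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
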