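Package: il6gnn
Title: Dual-Channel Graph Neural Classifier of IL-6-Inducing Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies short peptides as IL-6-inducing or not by representing
    each peptide as a residue graph. Adjacency is derived from predicted
    residue-pair distance-bin probability distributions thresholded into
    contact maps; node features fuse one-hot residue identity, sinusoidal
    position encodings, and PCA-reduced protein language-model embeddings.
    A dual-channel network (a three-layer multi-head graph attention channel
    and a one-layer graph convolution channel, each globally max-pooled)
    feeds a fully connected classifier trained with class-weighted binary
    cross-entropy. Includes imbalance-aware evaluation metrics, stratified
    cross-validation, grid search, ablation harnesses, fused-feature export,
    and a synthetic-data generator with a plantable class signal so the whole
    pipeline is testable without external structure predictors or language
    models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
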