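Package: SwarmSeg
Title: Similarity-Guided Swarm-of-Models Semi-Supervised Tissue Segmentation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Semi-supervised multi-class tissue semantic segmentation for
    whole-slide images using a similarity-guided swarm of per-case expert
    models. Annotated slides each train a "morphology expert"; unlabeled
    slides are matched to the most similar expert via K-means representative
    patch embeddings and mean pairwise cosine similarity, and pseudo-labels
    are produced by fusing the matched expert's tumor/tumor-stroma
    predictions with a pooled supervised model's predictions for the
    remaining classes. Includes deterministic tiling and mask I/O, a
    built-in histogram/gradient patch encoder with an adapter contract for
    external foundation encoders, pluggable segmentation backends, Dice /
    sensitivity / PPV evaluation with paired t-tests, and a seeded synthetic
    slide-cohort generator with per-case tumor morphology styles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite,
    EBImage,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Software, Segmentation, Classification
RoxygenNote: 7.3.3
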