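Package: tonguenet
Title: Multimodal Tongue-Image and Text Diagnosis with Dual-Space
    Representation Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-label classification of tongue images paired with
    structured textual sign records, for traditional Chinese medicine
    (TCM) diagnosis of disease nature (10 pathology syndromes) and
    disease location (9 organ regions). Implements a hierarchical
    aggregation image encoder with gated multi-granularity fusion, a
    structured-text encoder, projection of the fused representation
    into three complementary subspaces reweighted by multi-scale
    (height/width/global) grouped attention, and a Kolmogorov-Arnold
    classifier head with B-spline edge activations. Embeddings and
    label predictions live jointly in Euclidean space and on the
    Poincare ball; training combines binary cross-entropy with a
    cross-space consistency loss and a hyperbolic complementarity
    loss. Includes a reverse-mode automatic differentiation engine,
    an Adam trainer, evaluation metrics (accuracy, precision, recall,
    F1, mAP, AUC, Cohen's kappa), three-annotator consensus curation
    utilities, and a seeded generator of label-conditional synthetic
    tongue image/text datasets for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    splines,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
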