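Package: msfbel
Title: Multi-Scale Frequency-Band Ensemble Learning for EEG Feature Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of band-structured EEG feature tables (for example
    differential-entropy features with channels-by-bands layout) by multi-scale
    frequency-band ensemble learning. Adjacent frequency bands are grouped into
    patches at every scale, each patch is classified by an l2-regularized
    collaborative-representation classifier, patch labels are fused by majority
    voting within a scale, and per-scale labels are combined with ensemble
    weights learned on a validation split by minimizing a margin-based loss over
    the probability simplex with an augmented-Lagrangian scheme. Includes a
    class-conditional Gaussian generator for band-structured features with
    controllable per-band discriminability, evaluation utilities (confusion
    matrices, Nemenyi critical distance), and delimited-text import and export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
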