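Package: mstopics
Title: Multiscale Content Clustering of Free-Text Records with Markov Stability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Unsupervised discovery of content-based clusters in free-text
    document collections at multiple levels of resolution. Documents are
    normalised into token sequences, embedded as fixed-dimension vectors
    (PV-DBOW paragraph vectors or a TF-iDF baseline), connected into a
    sparsified geometric similarity graph (union of the minimum spanning
    tree and a k-nearest-neighbour graph), and partitioned across scales
    with Markov Stability, a diffusion-based multiscale community
    detection method. Robust scales are selected from variation-of-
    information diagnostics, and partitions are scored by intrinsic topic
    coherence (aggregate pointwise mutual information) and agreement with
    reference labels (normalised mutual information). Includes a synthetic
    corpus and graph generator with planted quasi-hierarchical structure
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
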