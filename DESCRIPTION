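Package: morphovae
Title: Landmark-Free Morphometrics with a Supervised Convolutional Variational Autoencoder
Version: 0.1.0
Authors@R:
    person("Morphovae", "Maintainers", email = "morphovae@example.org", role = c("aut", "cre"))
Description: Landmark-free analysis of three-dimensional biological shapes
    (exemplified by mammalian mandibles). Binary voxel volumes are oriented,
    split into mirrored halves and reduced to triplets of 128x128 silhouette
    projections; a convolutional variational autoencoder with a single-layer
    softmax classifier head compresses each triplet into a three-dimensional
    latent feature whose classes form separated clusters. Includes cluster
    separation metrics (pairwise separation index and Davies-Bouldin score),
    an RBF-kernel SVM readout of the latent space, PCA and plain-VAE
    baselines, latent-grid image generation, Score-CAM saliency maps,
    projection-direction ablation, a missing-segment (crop-rate) robustness
    experiment, and a synthetic shape generator so the full pipeline runs
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
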