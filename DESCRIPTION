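Package: tacclust
Title: Clustering of Time-Activity Curves in Dynamic Medical Images
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments 4D dynamic medical images (dynamic PET, dynamic
    contrast-enhanced MRI) by clustering per-voxel time-activity curves
    (TACs) into kinetic classes. Provides a hyperstack-style 4D image
    container with TAC extraction and voxel iteration, pluggable distance
    metrics (Pearson correlation distance, generalized p-norm, Mahalanobis
    with image covariance), clustering techniques (k-means with k-means++
    seeding, leader-follower, PCA, SVD, FastICA), a synthetic kinetic
    phantom generator with ground-truth labels, NIfTI/Analyze input,
    pseudo-dynamic label-image output, and TAC tables in CSV/TSV/PMOD
    dialects with frame timing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
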