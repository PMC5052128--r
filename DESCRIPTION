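Package: scribseg
Title: Minimally Interactive Multi-View Segmentation of Sparse Motion-Corrupted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Scribble-seeded interactive segmentation of anisotropic,
    motion-corrupted 3D MRI volumes. A user labels foreground and background
    in a single start slice; an online random forest over intensity, gray
    level co-occurrence and Haar wavelet patch features learns from the
    scribbles, a per-slice conditional random field solved exactly by
    max-flow regularises the prediction, and the segmentation propagates
    automatically to the remaining slices while the forest keeps learning
    from self-harvested seeds. Volumes of the same subject acquired in
    different views are then fused by a probability-based 4D graph-cut
    co-segmentation with intra-slice, inter-slice and inter-volume
    consistency terms. Includes a synthetic phantom generator for
    sparsely-sliced multi-view studies, evaluation metrics (Dice, average
    symmetric surface distance, Fleiss' kappa) and NIfTI input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
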