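Package: radsig
Title: Network-Based Radiomic Signature Selection for PET/CT Lesion Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Radiomic analysis pipeline for classifying locally recurrent
    rectal cancer (LRRC) from PET/CT lesion volumes. Provides PET voxel
    standardization (dose, decay and weight correction), nearest-neighbour
    transfer of lesion masks between PET and CT grids, extraction of a
    1223-dimensional radiomic feature vector (first-order, 3D shape and five
    texture-matrix families over original, wavelet- and Laplacian-of-Gaussian
    filtered images), network-based pairwise feature selection ranked by
    cross-validated Matthews correlation, and fold-averaged support-vector
    evaluation of the selected signatures. A synthetic-data module generates
    labelled feature tables with planted jointly-discriminative feature pairs
    and small two-class texture phantoms so the full pipeline runs without
    access to restricted patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    igraph,
    jsonlite,
    yaml,
    RNifti,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
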