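Package: srsc
Title: Spatially Regularized Spectral Clustering for Multiparametric MRI
    Tumor Segmentation
Version: 0.1.0
Authors@R:
    person("SRSC", "Maintainers", email = "srsc@example.org", role = c("aut", "cre"))
Description: Unsupervised segmentation of tumor tissue populations (necrotic,
    peri-necrotic, viable) from co-registered multiparametric MRI volumes
    (ADC, T2 and T2* pre/post contrast). Implements spatially regularized
    spectral clustering: an RBF affinity over voxel-wise feature vectors,
    a normalized graph-Laplacian embedding, and a Gaussian mixture EM whose
    responsibilities are weighted by the average responsibilities of each
    voxel's 26-connected image-space neighbors. Ships the baseline
    clusterers it is compared against (K-means, fuzzy C-means, standard
    GMM), tissue-fraction quantification with Pearson-correlation
    validation against reference fractions, class-wise nonparametric
    statistics, a synthetic multiparametric tumor phantom generator with
    ground truth, minimal NIfTI-1 volume I/O, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
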