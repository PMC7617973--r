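Package: premap
Title: Comparative Connectomics of the Mouse and Human Motor System
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Connectivity-based parcellation of a motor-cortex voxel
    territory from tracer-like projection volumes, with k-means model
    selection (stability, silhouette, inertia elbow, parcel-size variance);
    connectivity-fingerprint extraction over a fixed set of cross-species
    homolog targets, median template construction, and voxelwise fingerprint
    matching with sign-flip permutation inference (max-statistic or TFCE,
    family-wise error corrected); winner-take-all cross-species assignment
    and Kullback-Leibler spectral embedding of areas into a shared 2D
    connectivity space; and the supporting validation statistics
    (tracer-vs-fMRI voxelwise correlation with a conservative random-voxel
    null, Manhattan-distance permutation tests, double-angle B1+ mapping,
    paired ROI comparisons, perturbation-database meta-analysis). Includes
    seeded synthetic-data generators with planted ground truth for every
    input modality, so the full pipeline runs and is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    cluster,
    withr,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Clustering, Visualization, GraphAndNetwork
RoxygenNote: 7.3.3
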