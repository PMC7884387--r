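Package: paleoattrib
Title: Quantitative Attribution of Fossil Molars and Lithic Assemblages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative attribution of isolated hominin
    molars and associated lithic assemblages. Implements prediction-interval
    scaled ("adjusted") Z-score comparisons of single specimens against
    comparative group statistics, voxel-based 3D dental tissue proportions
    (lateral average and relative enamel thickness) and the volumetric
    bifurcation index of taurodontism, a landmark-based shape-analysis chain
    (curve resampling, generalized Procrustes analysis, PCA, between-group
    PCA with leave-one-out cross-validation, canonical variate analysis,
    a-posteriori projection of unknowns, allometry regression), and lithic
    attribute indices with normalization and PCA ordination. Synthetic
    generators for grouped landmark samples, voxelized tooth phantoms with
    closed-form compartment volumes, and lithic attribute tables make the
    whole pipeline testable without access to restricted fossil data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    EBImage,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
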