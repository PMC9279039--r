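Package: capsfmri
Title: Capsule-Network Classification of Resting-State fMRI Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and classification for resting-state fMRI
    depression studies. Computes the standard per-voxel activity maps
    (amplitude of low-frequency fluctuation and its fractional variant,
    Kendall-concordance regional homogeneity, correlation-threshold degree
    centrality) and atlas-level Pearson functional-connectivity matrices,
    classifies subjects with a capsule network trained by dynamic routing
    under a margin loss, fuses per-feature models into a weighted ensemble,
    and reports voxelwise two-sample group differences as connected-component
    cluster tables. Includes a deterministic synthetic-cohort generator so the
    whole pipeline can be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
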