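Package: kcmaps
Title: Corneal Thickness-Map Analytics for Keratoconus Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates corneal pachymetry, epithelial and axial-power maps for
    normal, keratoconic and topographically normal fellow eyes; extracts the
    fourteen zonal thickness variables used in OCT-based keratoconus screening;
    applies Placido-style topographic screening criteria (I-S, central power,
    KISA%); and quantifies diagnostic accuracy with cluster-aware ROC/AUC
    analysis, spline-based probability transforms for non-monotone markers and
    logistic multi-marker combination, with both eyes of a patient treated as
    a cluster.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    mgcv,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
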