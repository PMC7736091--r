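Package: hipmorph
Title: Contour-Based Radiographic Hip Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Semiautomatic measurement of hip-development indices on AP
    pelvis radiographs from manually traced bone contours. Given per-hip
    annotations (acetabular and femoral arc polylines, a marked sourcil
    medial point and a teardrop inferior point), the package localises the
    femoral head centre by a three-point circumcircle fit, derives the
    acetabular landmarks, and computes the Toennis, Sharp and centre-edge
    (CE) angles in a pelvic frame anchored on the inter-teardrop line.
    Threshold and SVM classifiers map angles to development labels
    (normal / borderline / dysplasia), and an evaluation module provides
    the agreement and diagnostic statistics used to validate such systems
    against a reference reader (confusion tables, accuracy / sensitivity /
    specificity, Cohen's kappa, exact McNemar and Bowker tests, Pearson
    correlation, Cronbach's alpha, ROC / AUC with Youden threshold
    selection). A geometric phantom generator produces annotations with
    known ground-truth angles, and a cohort simulator produces paired
    physician / CAD measurements for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    e1071,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'hipmorph-package.R'
    'conditions.R'
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'annotation-io.R'
    'landmarks.R'
    'angles.R'
    'classification.R'
    'evaluation.R'
    'roc.R'
    'phantom.R'
    'cohort.R'
    'reference-tables.R'
    'cli.R'
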