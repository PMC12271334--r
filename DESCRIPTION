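Package: ppgv
Title: Personalized Prediction and Vulnerability Profiling of Postprandial Glucose Excursions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Pipeline for idiographic (per-individual) modelling of postprandial
    glucose excursions from continuous glucose monitor (CGM) traces, meal logs and
    glucose-lowering-agent logs. Computes each meal's 2-hour incremental area under
    the curve, labels excursions against an expanding personal baseline, builds
    low-burden (temporal-only) and high-burden (meal and medication) feature sets,
    fits per-person gradient-boosted-tree classifiers with rolling-origin
    cross-validated grid search, compares the two feature sets with paired Wilcoxon
    signed-rank tests, and derives normalized feature-importance vulnerability
    profiles. Ships a seedable synthetic-cohort generator with known ground-truth
    excursion drivers for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    xgboost
Suggests:
    ggplot2,
    readxl,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
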