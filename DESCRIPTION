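Package: ropvitals
Title: Early Prediction of Laser-Requiring Retinopathy of Prematurity
    from Neonatal Vital-Sign Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing 30-day neonatal physiological monitor
    data (SpO2, heart rate, FiO2) to predict retinopathy of prematurity
    requiring laser treatment. Provides daily feature extraction
    (oxygenation burden, desaturation/bradycardia/tachycardia events,
    SpO2/FiO2 ratio, distribution skewness), non-parametric cluster-based
    permutation testing for group-different time windows, an
    imbalance-aware leave-one-out random-forest classification protocol
    with random undersampling, evaluation metrics with Agresti-Coull
    intervals and mid-p McNemar model comparison, and a synthetic cohort
    generator for end-to-end validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    e1071,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
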