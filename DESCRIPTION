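Package: NutriVision
Title: Nutrient-Deficiency Classification from Leaf Images with Ring Toss Game Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying macro- and micro-nutrient
    deficiencies (nitrogen, phosphorus, potassium, calcium, iron) from RGB leaf
    images. Stages: Gabor-filter texture pre-processing, K-means region-of-interest
    segmentation, a compact SqueezeNet-style convolutional feature extractor trained
    with a from-scratch Adam optimizer, a hybrid CNN-LSTM classifier with parallel
    coarse (deficient vs healthy) and fine (six-class) heads, and the Ring Toss Game
    Optimization (RTGO) population metaheuristic for hyperparameter tuning. Includes
    a seeded synthetic leaf-image generator with six stylized deficiency phenotypes
    so the full pipeline is testable without field imagery, plus one-vs-rest
    multiclass metrics (accuracy, precision, recall, specificity, F-score, MCC) with
    macro averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
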