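Package: pfpress
Title: Classification of Pelvic Floor Pressure Distribution Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating continent from incontinent women using
    intravaginal spatiotemporal pressure profiles recorded by a 10 x 10
    capacitive sensor matrix during four pelvic floor maneuvers. Provides a
    seeded synthetic cohort generator, sensor-grouping supersets (quadrants,
    bands, planes, rings and their intersections), zero-phase Butterworth
    preprocessing, formula-defined feature extraction (peak/sum extrema and
    instants, activation instant, pressure integrals, plateau duration,
    contraction and relaxation rates, covariance features), two-stage feature
    selection (Pearson/RELIEF ranking followed by branch-and-bound under the
    Mahalanobis class-separability criterion or recursive feature elimination
    with random-forest importance), and nested leave-one-out model selection
    and evaluation of k-nearest-neighbour, logistic-regression and linear
    support-vector classifiers, with McNemar paired comparisons, top-feature
    statistics and PCA projections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    randomForest,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
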