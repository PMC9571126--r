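Package: ffqreduce
Title: Personalised Reduction of Food Frequency Questionnaires by
    Multi-Target Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Shrinks a 24-item grid-style Food Frequency Questionnaire (FFQ)
    to a small question subset (4, 6, 9 or 12 items) while predicting eleven
    nutrition-goal quality scores by multi-target linear regression.
    Implements cross-validated feature-importance ranking, a personalised
    weighting scheme that emphasises goals whose predicted scores violate
    their thresholds, a seeded synthetic-population generator with
    block-correlated food groups, and a three-arm experiment driver
    (random / statically optimised / personalised question selection)
    with tidy result aggregation and plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
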