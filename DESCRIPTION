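Package: metalsource
Title: Heavy-Metal Pollution Assessment and Source Apportionment for
    Soil-Plant Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing heavy-metal contamination in paired
    soil-plant surveys and attributing it to candidate pollution sources.
    Implements the single-factor, Nemerow composite, and Hakanson
    potential-ecological-risk indices with standard classification
    schemes; bioconcentration factors, exceedance folds against plant
    standards, soil-plant Pearson correlation matrices, and nonparametric
    group-difference tests; the APCS-MLR receptor model (absolute
    principal component scores with per-metal multiple linear regression
    and percent source contributions including an unidentified term); and
    random-forest source apportionment from distance-decay proximity
    features with R-squared, RMSE, MAE, and RPD evaluation.  A synthetic
    survey generator produces paired soil-plant data with known source
    structure for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
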