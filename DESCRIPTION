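Package: mdsqi
Title: Soil Quality Indices from Minimum Data Sets for Mine Waste Dumps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evaluates soil quality of reclaimed open-pit mine waste dumps
    from panels of physicochemical indicators. Measured values are rescaled
    to fuzzy membership scores on [0.1, 1] with S-type and parabolic
    membership functions; a minimum data set (MDS) of indicators is selected
    by correlation-matrix principal component analysis combined with Norm
    values, cross-loading grouping and Pearson redundancy filtering;
    indicator weights are derived from PCA communalities; and composite soil
    quality indices are computed by the weighted-additive method and by an
    improved Nemerow (minimum-factor) index, with fertility classification.
    Includes transcriptions of published reference tables and a seeded
    multivariate-normal synthetic data generator so the full pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
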