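Package: fpir
Title: Fractional-Power Interaction Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates fractional exponents in the interaction term of a
    multiple linear regression. The interaction between two continuous
    predictors X1 and X2 is modelled as beta3 * X1^M * X2^N with real-valued
    exponents M and N chosen by a two-stage grid search (55 candidate values
    per exponent from -52.5 to 52.5, then 10 tuned values around the initial
    winner, 550 reachable values per exponent within [-56, 56]). Includes an
    ordinary-least-squares engine reporting sequential (Type I) sums of
    squares and two AIC conventions, comparator models (regular interaction
    regression, bivariate polynomial regression, and the quadratic-augmented
    variant), an R-squared surface and simple-slope diagnostics, a seeded
    synthetic-data generator with parameter-recovery experiments, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
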