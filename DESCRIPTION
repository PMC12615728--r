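Package: dietshift
Title: Acceptability-Weighted Diet Optimization with Novel Foods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quadratic goal programming for designing culturally acceptable,
    nutritionally adequate, low greenhouse-gas-emission diets that introduce a
    novel food (for example mycoprotein) into an observed diet. The model
    minimizes popularity-weighted, standard-deviation-standardized deviations
    from the current diet at food-category and food-group level, using split
    positive/negative deviation variables so increases and decreases can be
    penalized differently, subject to nutritional bounds, an energy equality,
    percentile-based feasible consumption ranges, fixed categories, a total-mass
    band, and stepwise greenhouse-gas caps. Includes a piecewise-linear
    comparator model, a scenario ladder runner, sensitivity-analysis variants,
    reporting tables, and a synthetic dietary-survey generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    quadprog,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nloptr
Config/testthat/edition: 3
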