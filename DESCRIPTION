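Package: tractrisk
Title: Census-Tract Health Risk Factor Modeling by Spatial Microsimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds census-tract-resolved synthetic populations by combinatorial
    reweighting of coarse-geography microdata against small-area constraint
    tables using simulated annealing, fits chained logistic and linear outcome
    models (exercise, fruit and vegetable consumption, body mass index,
    diabetes) from survey data with block-wise backward selection, applies the
    model chain to the synthetic population of adults aged 21 and older, and
    propagates uncertainty by Monte Carlo simulation to tract-level prevalence
    estimates, percentile intervals, and coefficients of variation. Includes a
    synthetic-data generator that emulates the structure of American Community
    Survey constraint tables, public-use microdata samples, and Behavioral Risk
    Factor Surveillance System survey records, so the full pipeline can be
    exercised and validated against known ground truth without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
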