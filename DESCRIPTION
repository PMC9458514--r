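Package: pdaccea
Title: Cost-Effectiveness Modelling of Neoadjuvant Chemotherapy in
    Borderline-Resectable Pancreatic Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A monthly-cycle Markov cohort model comparing neoadjuvant
    FOLFIRINOX, gemcitabine plus nab-paclitaxel, and untreated natural
    history for borderline-resectable/locally-advanced pancreatic ductal
    adenocarcinoma. Includes calibration of piecewise-constant monthly
    transition probabilities to published overall- and progression-free
    survival summaries, discounted cost and QALY accounting with
    half-cycle correction, incremental cost-effectiveness ratios on the
    efficiency frontier, one-way deterministic sensitivity analysis,
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, and a scenario-override mechanism.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
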