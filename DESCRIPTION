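Package: osteocea
Title: Cost-Effectiveness Microsimulation of Fracture Prevention During
    Aromatase-Inhibitor Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A Markov microsimulation framework for evaluating the
    cost-effectiveness of bone-mineral-density screening and
    anti-osteoporotic therapy in postmenopausal women with hormone
    receptor-positive early breast cancer receiving aromatase inhibitors.
    Provides pseudo-individual-patient-data reconstruction from digitized
    Kaplan-Meier curves, parametric survival fitting with AIC model
    selection, age- and BMD-dependent fracture risk modelling, a
    common-random-number first-order Monte Carlo engine over a combined
    cancer-fracture state space, incremental cost-effectiveness analysis
    with an extended-dominance frontier, deterministic and probabilistic
    sensitivity analyses (tornado diagrams, cost-effectiveness
    acceptability curves), and a scenario grid over starting age, risk
    group, screening interval, adherence, drug, perspective and horizon.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    flexsurv,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
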