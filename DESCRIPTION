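Package: adentropy
Title: Entropy-Guided Machine Learning for Anaerobic Digestion Operation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Soft-sensor modelling and entropy-based uncertainty analysis for
    industrial anaerobic digestion. Generates synthetic plant records with
    configurable marginals and correlation structure, implements a shared
    cleaning/scaling/splitting protocol, trains support vector machine,
    random forest and neural-network predictors of biogas yield, reactor
    temperature and volatile fatty acid concentration, quantifies predictive
    uncertainty by kernel-density error entropy and permutation entropy
    increase, scores operational stability by process entropy over discrete
    operating states, simulates advisory (model-assisted) operation against a
    baseline, and provides techno-economic scaling, discounted payback and
    grid-emission-factor carbon accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
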