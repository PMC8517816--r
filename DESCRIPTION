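Package: emibayes
Title: Expert-Elicited Bayesian Network Engine for Momentary Mental-Health Advice
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Discrete Bayesian network decision engine for ecological momentary
    assessment and intervention in suicide-relapse prevention. Estimates the
    momentary level of clinical dimensions (anxiety, mood, sleep, ...) from
    four-level questionnaire answers by naive-Bayes inference, aggregates them
    over time with an exponential forgetting factor, infers a contextual
    severity per dimension from the immediate and cumulated levels, and scores
    pre-established advice through noisy-OR models. Ships the expert-elicited
    knowledge base (structure plus all conditional probability tables), a
    validator and elicitation helpers (roulette / per-100 count conversion),
    an exhaustive-enumeration inference oracle for testing, an in silico
    patient simulator implementing extreme-profile and 15-scoring worsening
    scenarios, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
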