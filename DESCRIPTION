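Package: obesitydyn
Title: System Dynamics of Social Transmission of Obesity-Related Behaviors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compartmental stock-and-flow model of the social transmission of
    obesity-related behaviors across adult and child populations. Six stocks
    (normal weight, overweight, obese, for adults and children) evolve under
    adult-to-adult, adult-to-child and child-to-child transmission, overweight
    to obese progression, and weight-loss recovery flows. Prevention and
    treatment interventions act as linear ramps on transmission rates and
    weight-loss engagement proportions, with cross-age impact coupling.
    Includes parameter-estimation helpers for survey-style records, a
    two-way transmission-rate sensitivity analysis, a scenario-by-alternative
    intervention sweep with ranking by final childhood overweight and obesity
    prevalence, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
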