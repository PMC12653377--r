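Package: cdmpath
Title: Learning Pathways and Progressions from Cognitive Diagnostic Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline that turns dichotomous test responses and a
    Q-matrix into fine-grained diagnostic results. A mixed cognitive diagnostic
    model (saturated G-DINA with item-level Wald-test selection of reduced
    families) is estimated by marginal maximum likelihood EM, examinees are
    classified into knowledge states by maximum a posteriori estimation, the
    observed states are arranged into a stratified first-order learning-pathway
    network with a dominant trajectory, and a tiered learning progression is
    built by absorbing rare states into dominant clusters and scaling states on
    a two-parameter logistic IRT ability metric. A synthetic-cohort generator
    with a higher-order latent-trait attribute population supports testing
    every stage without confidential exam data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
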