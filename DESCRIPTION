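Package: repsel
Title: Variance Decomposition and the Repeatable Opportunity for Selection
Version: 1.0.0
Authors@R:
    person("repsel", "developers", email = "repsel@example.org",
           role = c("aut", "cre"))
Description: Decomposes variance in male reproductive success measured in
    sequential mating groups into four multiplicative pre- and postcopulatory
    fitness components (partner fecundity, mating success, sperm-transfer
    efficiency, sperm fertilizing efficiency), corrects derived components for
    binomial sampling error, estimates the repeatability (intraclass
    correlation) of each component across independent mating groups with a
    Gaussian random-intercept model, and combines the two into the repeatable
    opportunity for selection I_R = R x I with bootstrap percentile inference
    and signed-difference tests. Includes a generative simulator of the
    mating-group design (focal-specific latent quality, group-level noise,
    batch effects, Poisson/binomial observation layers) so every stage of the
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
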