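Package: ipmviability
Title: Multistate Integral Projection Models and Population Viability Analysis
    for Perennial Plant Census Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cleans multi-year tagged-plant census records into a three-state
    life cycle (normal rosette, bolter, vegetatively dormant), including the
    "reincarnation" correction of survival histories that reveals aboveground
    dormancy; fits size-dependent vital-rate regressions with random year
    intercepts and AICc model selection; assembles annual multistate integral
    projection model (IPM) kernels on a shared size mesh; estimates stochastic
    population growth rates, transient population projections and extinction
    probabilities with parametric-bootstrap uncertainty; and correlates the
    demographic outcomes with population-genetic summary statistics, including
    a small-sample power analysis for Pearson correlations. A synthetic census
    generator with known ground-truth parameters supports end-to-end testing
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    lme4,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
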