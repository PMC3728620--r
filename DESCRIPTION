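Package: pHendo
Title: Activity-Dependent Synaptic Vesicle Endocytosis Kinetics from
    pHluorin Fluorescence Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling and analysing synaptic vesicle
    endocytosis kinetics measured with pHluorin-based reporters
    (e.g. vGlut-pHluorin). Provides a stochastic per-vesicle simulator of
    baseline-subtracted fluorescence traces whose endocytic time constant
    is modulated by stimulus history (a saturating, persistent
    acceleration state plus linear activity-dependent slowing),
    temperature, external calcium and dynamin genotype; the standard
    decay-fitting protocols (single exponential with a reacidification
    temporal offset, inverse-rate linear fits, remaining-fraction
    metric, rising-exponential bafilomycin fits); a closed-form
    biexponential endocytosis/reacidification model with a fit-bias
    analysis for mis-specified reacidification; and an analysis pipeline
    reproducing tuning curves of the endocytic time constant versus
    stimulus number, burst-persistence protocols and population
    statistics, including parameter-recovery validation on synthetic
    populations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
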