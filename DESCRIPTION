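Package: synaptr
Title: Tsodyks-Pawelzik-Markram Synapse Modeling, Trace Fitting, and
    Deep-Learning Normalization of Synaptic Physiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven analytic simulation of the simplified three-state
    Tsodyks-Pawelzik-Markram (TPM) short-term plasticity model with a
    four-state ODE reference oracle, conversion of conductances to
    voltage-clamp currents and current-clamp potentials, standardized
    nine-point reconstruction of digitized synaptic traces, bounded
    differential-evolution fitting of the five synapse parameters
    (conductance, decay, recovery, facilitation, utilization), a
    SMAPE-loss multilayer-perceptron normalization stage that imputes,
    disambiguates and normalizes fitted parameters across experimental
    covariates, and the accompanying statistics layer (symmetric
    percentage distance, trimmed means, Wilcoxon comparisons with FDR
    correction, grouping coefficients of variation, covariate effects,
    parameter correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    pracma,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
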