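Package: ctspec
Title: Corticothalamic Neural-Field Simulation and Aperiodic/Periodic EEG
    Spectral Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools linking emotional arousal to EEG spectral features through
    a corticothalamic neural mass model. Simulates the global mode of a
    four-population (cortical excitatory/inhibitory, thalamic relay and
    reticular) neural field with corticothalamic conduction delays by
    Euler-Maruyama integration, and characterizes how aperiodic (offset,
    exponent) and periodic (alpha peak) spectral features depend on synaptic
    couplings. Includes multitaper (DPSS) power spectral estimation,
    parameterization of spectra into a Lorentzian aperiodic component plus
    Gaussian peaks, linear mixed models with Satterthwaite F-tests and Holm
    correction for trial-level arousal/valence effects, and a seeded
    generator of DEAP-shaped synthetic studies with known ground truth for
    end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
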