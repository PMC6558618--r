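Package: eeguq
Title: Uncertainty Quantification for EEG Dipole Reconstruction under
    Conductivity Uncertainty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the effect of head-tissue conductivity uncertainty on
    EEG single-dipole source reconstruction. Provides an analytic multilayer
    concentric-sphere volume conductor and leadfield assembly, goal-function
    scan dipole fits (fixed, rotating, moving), generalized polynomial chaos
    surrogates of the leadfield over uniformly distributed tissue
    conductivities with Smolyak sparse-grid collocation, coefficient-based
    Sobol sensitivity indices, topography and magnitude error metrics
    (RDM, lnMAG), and a synthetic somatosensory-evoked-potential scenario
    generator, orchestrated into univariate and multivariate
    uncertainty-quantification experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
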