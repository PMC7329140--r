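Package: hsnn
Title: Hierarchical Spiking Neural Network Model of the Ascending Auditory Pathway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a six-layer hierarchical spiking neural network (HSNN)
    model of the ascending auditory pathway and evaluates it on a word
    recognition-in-noise task. Provides a gammatone cochlear front end, leaky
    integrate-and-fire layers with Gaussian excitatory/inhibitory tonotopic
    connectivity under power-law layer scaling, a Bernoulli naive-Bayes
    spike-train word decoder with leave-one-out cross-validation, a grid-search
    optimizer over the layer scaling exponents, single-layer linear-Poisson and
    linear-nonlinear-Poisson receptive-field baselines, and a characterization
    suite (spectro-temporal receptive fields by reverse correlation, Gabor
    receptive-field fits, direct-method mutual information, trial-based
    signal/noise response spectra, band SNR and modulation index). A synthetic
    digit-like speech corpus generator, speech-babble noise, and dynamic moving
    ripple probe stimuli make every experiment runnable without licensed
    speech data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
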