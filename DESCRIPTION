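Package: superspike
Title: Superstatistical Analysis of Cortical Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the superstatistical description of irregular neuronal
    firing. Simulates doubly-stochastic gamma renewal spike trains whose latent
    firing rate is itself gamma distributed, builds logarithmically binned
    inter-spike-interval (ISI) histograms, classifies power-law versus
    exponential tails by linear regression, fits the generalized beta
    distribution of the second kind (beta-2) to ISI histograms, decomposes it
    into a gamma firing-rate distribution, and evaluates the information
    measures (firing-rate entropy, conditional response entropy, ISI entropy,
    mutual information) that discriminate between entropy-maximization coding
    hypotheses (MFE, CMFE, MMI) for cortical neurons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
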