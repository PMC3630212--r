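Package: ppcharm
Title: Multisensory Integration by Density Estimation with Population Codes and Harmoniums
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates probabilistic population codes for limb position (Gaussian
    tuning curves with independent Poisson spike counts), trains an
    exponential-family harmonium (Poisson visible units, Bernoulli hidden units)
    with one-step contrastive divergence to model the joint distribution of
    visual and proprioceptive population activity, and decodes the full Gaussian
    posterior over the stimulus from the hidden layer via the generative
    weights. Includes closed-form optimal-posterior benchmarks, KL-divergence
    and fractional-information-loss evaluation, experiment protocols for cue
    integration, prior learning, sometimes-decoupled cues, hierarchical
    integration and coordinate transformation, and hidden-unit tuning-curve and
    reference-frame analyses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
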