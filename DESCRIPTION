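Package: crossrbm
Title: Cross-Subject Mapping of Neural Features with Gauss-Bernoulli
    Restricted Boltzmann Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits Gauss-Bernoulli restricted Boltzmann machines to
    multi-subject neural feature data by either score matching (Fisher
    divergence minimisation with closed-form gradients) or k-step
    contrastive divergence, and uses conditional Gibbs sampling from the
    fitted joint distribution to transfer feature vectors of target
    subjects into the feature spaces of source subjects, so that linear
    decoders trained on source subjects can classify target trials.
    Includes Gaussian-kernel smoothing of spike trains with per-subject
    PCA feature extraction, a synthetic multi-subject data generator, a
    repeated-split evaluation harness with subject-specific and
    no-transfer baselines, and plain-text readers and writers for all
    file formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
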