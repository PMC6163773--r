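Package: aharTL
Title: Audio-Based Human Activity Recognition with Transfer-Learning Data Augmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Recognizes everyday human activities from the sounds they produce,
    with a transfer-learning module that augments activity classes holding
    little audio data. Clips are parameterized with multidomain frame features
    (Mel-frequency cepstral coefficients with velocities, MPEG-7 spectral
    descriptors, and perceptual wavelet-packet features); per-class Gaussian
    mixture densities and a Monte Carlo symmetrized Kullback-Leibler divergence
    identify, for each data-poor class, its statistically closest donor class;
    an echo-state (reservoir) network learns a multiple-input multiple-output
    mapping from donor to limited feature space and synthesizes additional
    training material; recognition uses class-specific left-right hidden Markov
    models or a universal ergodic model with per-class adaptation. Includes a
    cross-validated evaluation pipeline, a deterministic synthetic-corpus
    generator for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
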