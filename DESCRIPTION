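Package: alsasnn
Title: Associative-Learning Supervised Training for Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clock-driven simulation of conductance-based leaky
    integrate-and-fire neurons with adaptive firing thresholds, a modified
    spike-timing-dependent plasticity rule with heterosynaptic long-term
    depression, and a teacher-layer supervised training procedure (ALSA) in
    which all weight changes are produced by the local plasticity rule while
    supervision enters only as induced spiking of class-specific teacher
    neurons. Includes triangle population-rate and latency encoders, Poisson
    spike sources, winner-take-all lateral inhibition, unsupervised feature
    learning, and reproducible classification pipelines for the Fisher iris
    table and grayscale digit images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
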