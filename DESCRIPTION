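Package: idnet
Title: Feedforward Sequence Identification Networks with Activity-Dependent Node Silencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates and trains identification networks (ID-nets):
    feedforward spiking (leaky integrate-and-fire) and continuous-activation
    classifiers whose input and hidden nodes are temporarily silenced in
    proportion to their recent activity.  Because each object in a timed
    sequence then acts on a different dynamically created sub-network, a
    network without feedback loops can recognise the order and timing of a
    whole sequence of handwritten digits, reject test sequences that are too
    fast, too slow or wrongly ordered, and authenticate a writer through a
    minimal output-gap score.  Includes Bernoulli rate-coded frame encoding
    of gray-level images, a synthetic glyph generator with per-writer noise,
    an IDX (MNIST-format) reader, per-digit backpropagation with silenced
    terms removed, and threshold/specificity decision analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
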