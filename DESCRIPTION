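Package: qtremor
Title: Quantum-Inspired Hybrid Networks for Essential-Tremor Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for grading essential-tremor severity from multi-finger
    capacitive-sensor recordings rendered as 640x10 grayscale images. Implements
    an exact statevector simulator for small qubit registers, the Quantvolution
    pixel-graph circuit filter (Hadamard + Ising XX/ZZ couplings on a ring of
    edge qubits), a two-qubit QuantClass decision head trained with the
    parameter-shift rule, compact classical and hybrid convolutional networks
    with Adam and polynomial learning-rate decay, a seeded generator of synthetic
    tremor recordings in the sensor image format, and a six-configuration
    ablation harness with one-way ANOVA and Tukey HSD reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    yaml,
    jsonlite,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
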