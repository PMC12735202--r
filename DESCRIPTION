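Package: quadspec
Title: Quadratic-Neuron 1-D Convolutional Networks for Vis/NIR Fruit Grading
Version: 0.1.0
Authors@R:
    person("quadspec", "developers", email = "quadspec@example.org",
           role = c("aut", "cre"))
Description: Toolkit for grading internal fruit disorders from visible/
    near-infrared (Vis/NIR) transmission spectra. Implements a
    one-dimensional convolutional classifier whose first layer uses
    quadratic neurons, the matching linear-convolution ablation baseline,
    chemometric preprocessing (SNV, MSC, min-max scaling, column
    standardization), SPXY and stratified sample partitioning, a labelled
    synthetic-spectrum generator, and a slice-stack volumetric quantifier
    that turns serial cross-section masks into a watercore volume fraction
    and a 4-level grade.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
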