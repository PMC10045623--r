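Package: remoraCNN
Title: Remora Swarm Optimization of Convolutional Network Hyperparameters
    for CT Texture Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A multi-process remora optimization algorithm (a swarm
    metaheuristic combining sailfish-style elite following, whale-style
    spiral exploitation and host-feeding local search) applied to the
    two-phase optimization of a small convolutional classifier: phase one
    searches the network structure (counts of convolution, pooling and
    fully connected layers), phase two the eight shared layer
    hyperparameters.  Includes CT-style image preprocessing (conditional
    mean impulse filtering, tiled adaptive histogram equalization), a
    14-value wavelet/GLCM/histogram feature extractor, multiclass
    evaluation metrics, a reproducible 4-class synthetic lung-CT phantom
    generator and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
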