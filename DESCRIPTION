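Package: canqpi
Title: Simulated Quantitative Phase Imaging Microscopy with Deep-Learning
    Phase Retrieval
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a high-numerical-aperture reflection microscope
    imaging uniform layered samples (plasmonic gold films and lossless
    dielectric waveguides) via Fresnel/transfer-matrix optics and a
    vectorial 512x512 back-focal-plane pupil, propagates defocused
    image-plane intensities by Fourier optics, generates supervised
    datasets of intensity channels with ground-truth wrapped-phase labels,
    trains a context aggregation network (exponentially dilated
    convolutions with adaptive normalization) to regress the back-focal-
    plane phase, and scores recovered phase maps with an offset-invariant
    structural similarity index and confocal V(z) curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
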