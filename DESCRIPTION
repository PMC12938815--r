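Package: vsdecode
Title: Simulation and Decoding of Cortical Voltage-Sensitive Dye Responses
    to Retinal Neuromorphic Microstimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Proof-of-concept simulation loop for an intracortical visual
    prosthesis driven by retinal neuromorphic spike trains. Encodes grayscale
    images into retina-like spike trains (difference-of-Gaussians spatial
    filtering, biphasic temporal filtering, Izhikevich spike generation),
    transforms spike trains into simulated cortical voltage-sensitive dye
    (VSD) responses with an experimentally motivated Wiener system
    (Lorentzian pulse broadening, linear temporal filter, modified-Softplus
    static gain), and decodes images back from spikes or simulated VSD
    streams with small 3-D convolutional networks trained with binary
    cross-entropy and structural-similarity losses. Includes Wiener-system
    identification (cross-correlation filter estimate, nonlinearity fit),
    SSIM and Fourier-domain reconstruction metrics, and a fixed-frequency
    stimulation baseline with pulse-budget matching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    png,
    tiff,
    stats,
    utils,
    ggplot2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
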