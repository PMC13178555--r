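Package: ramanunmix
Title: Machine-Learning-Augmented Spectral Unmixing of Raman Spectra for
    Adjuvanted Protein Formulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying a protein antigen adsorbed to an
    aluminium-hydroxide adjuvant from Raman spectra of dried sample spots.
    Implements the full workflow: spectral preprocessing (cropping, cosmic
    spike removal, iterative polynomial baseline correction, internal-standard
    normalization), contextual out-of-distribution data augmentation (CODI),
    a concentration-anchored convolutional autoencoder for blind unmixing,
    non-negative least squares and multivariate curve resolution (MCR-ALS)
    baselines, evaluation metrics (cosine distance, spectral angle distance,
    concentration mean squared error, inverse coefficient of variation,
    recovery and relative standard deviation), and a synthetic model-vaccine
    spectra simulator with adsorption saturation, coffee-ring spatial
    heterogeneity, baseline drift and cosmic spikes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
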