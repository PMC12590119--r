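Package: amblyosim
Title: Simulation and Quantification of Amblyopic Visual Distortions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models distorted visual percepts in amblyopia as saturated
    weighted sums of rectified sinusoidal gratings, fits the model to
    perceptual drawings by minimizing a normalized Laplacian pyramid
    distance (NLPD) with iterative Nelder-Mead filter addition, and
    quantifies distortion magnitude, contrast-sensitivity deficits,
    predicted cortical activation spread on orientation-preference maps,
    and contrast-dependent spatial-frequency tuning of thalamic neurons.
    Includes seeded synthetic-data generators (drawings, contrast
    sensitivity tables, orientation maps, subject cohorts) so every stage
    can be exercised end to end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    minpack.lm,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
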