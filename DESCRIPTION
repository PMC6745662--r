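Package: movestate
Title: Hidden Markov Models for Behavioral States in Animal Movement Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies GPS movement tracks of nocturnally tracked animals into
    latent behavioral states (denning, foraging, fast-traveling) with hidden
    Markov models using gamma step-length and von Mises turning-angle emission
    distributions, and relates state switching to habitat structure through
    covariate-dependent multinomial-logit transition probabilities. Includes
    regularization of raw fix tables into nightly 15-minute tracks with missing
    slots, habitat covariate layers (NDVI, K-means vegetation-density classes,
    Euclidean distance to woodland edge, canopy cover), maximum-likelihood
    fitting with multiple starts, Viterbi decoding, one-step-ahead
    pseudo-residual diagnostics, stationary-distribution covariate profiles,
    AIC model tables, and a synthetic landscape-and-track generator with known
    parameters for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
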