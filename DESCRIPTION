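Package: oscsme
Title: Oscillatory Subsequent-Memory Effects in Item-Context Association EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of oscillatory subsequent-memory effects (SME) in an
    item-context association task: Morlet wavelet time-frequency decomposition of
    multichannel EEG epochs, single-trial and condition-level baseline t-normalization,
    group-level dependent-samples linear regression across memory outcomes with
    cluster-based Monte Carlo permutation correction over channel x frequency x time,
    frequency-and-region-of-interest (FROI) summarization of single trials, and
    random-intercept logistic mixed models fitted by adaptive Gauss-Hermite quadrature
    that predict item-only versus pair memory from theta and alpha/beta power with an
    age moderator. Includes a synthetic-data generator that emulates the study design
    (scene-object encoding lists, constrained test orderings, miss/item-only/pair
    outcomes) and the oscillatory effect structure (1/f background, theta bursts,
    alpha/beta desynchronization driven by a latent encoding strength), so the whole
    pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
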