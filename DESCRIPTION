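Package: nof1relapse
Title: Personalized Relapse Prediction from Wrist Actigraphy and Weekly Self-Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An N-of-1 framework for near-term prediction of depressive relapse.
    Minute-resolution wrist activity counts are screened for gaps and artifacts,
    summarized into daily fractal and entropy features (detrended fluctuation
    analysis exponents, multifractal spectrum width, sample entropy over the day
    and four six-hour epochs), and monitored with a per-patient LSTM
    encoder-decoder whose Mahalanobis reconstruction-error score is thresholded
    adaptively. Passive anomalies are confirmed against weekly depression and
    anxiety self-reports before a relapse flag is raised, and visit-level
    performance is summarized with balanced accuracy, false-alarm, burden and
    lead-time metrics. A synthetic cohort generator with controllable fractal
    structure, latent severity trajectories and labeled bimonthly clinic visits
    makes the whole pipeline testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
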