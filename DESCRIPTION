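Package: envdyn
Title: Power-Envelope Connectomics and Transient State Dynamics for
    Oscillatory Brain Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Resting-state electrophysiological network analysis at the level
    of band-limited power envelopes. Builds leakage-corrected envelope
    correlation connectomes over canonical resting-state networks using
    pairwise signal orthogonalization; models transient network dynamics with
    a Gaussian-observation hidden Markov model on group-concatenated,
    PCA-prewhitened envelopes, including Viterbi state decoding, state
    temporal metrics (mean lifetime, fractional occupancy, mean interval
    length) and state power maps; tests group differences with Kruskal-Wallis
    and Tukey's range test on ranks under effective-comparison Bonferroni
    correction; and generates synthetic oscillatory cohorts with planted
    connectivity, power and state-dynamic effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
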