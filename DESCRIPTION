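Package: primpulse
Title: Contact-Free Cardiac Signal Estimation from Video of Unrestrained Primates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates heart rate and interbeat intervals from ordinary video
    of unrestrained primates using the motion-based (ballistocardiographic)
    principle: subtle head and body movements driven by cardiopulmonary
    activity modulate the light intensity reflected from the face. The
    pipeline tracks a facial region of interest with a MOSSE correlation
    filter, extracts the mean luma (Y) trace, isolates the cardiac component
    with a third-order Butterworth band-pass followed by complete ensemble
    empirical mode decomposition with adaptive noise (CEEMDAN), and converts
    detected pulse peaks into windowed heart rate and interbeat intervals.
    Includes validation statistics against a reference pulse trace (mean
    error, Pearson correlation, two-sample Kolmogorov-Smirnov test on
    interbeat-interval distributions) and a synthetic video generator with
    known cardiac ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    jsonlite,
    png,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
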