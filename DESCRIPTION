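Package: radarbeat
Title: Contactless Heartbeat Detection from Continuous-Wave Doppler Radar
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects individual heartbeats from the raw in-phase/quadrature (I/Q)
    baseband channels of a 24 GHz continuous-wave Doppler radar. A shallow
    feed-forward neural network, trained with Levenberg-Marquardt optimisation
    against an ECG-derived binarized target (a 400 ms pulse delayed 200 ms after
    each R wave), maps 1 s windows of decimated I/Q samples to a per-sample beat
    probability; moving-average smoothing, prominence-constrained peak picking and
    doubled-interval interpolation turn the probability trace into discrete beat
    events. Includes a physics-based synthetic cohort generator (beat trains,
    ballistocardiographic chest displacement, quadrature baseband synthesis with
    imbalance/offset/noise, and a matched synthetic ECG), Pan-Tompkins R-peak
    detection, extended differentiate-and-cross-multiply (DACM) phase
    demodulation diagnostics, and subject-wise cross-validated evaluation with
    count-error and inter-pulse-interval statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    nortest,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
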