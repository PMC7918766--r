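Package: painreact
Title: Multimodal Pain-Related Reaction Assessment for Manual Physiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing pain-related reactions from synchronized
    multimodal physiological recordings (electrodermal activity,
    electromyography, respiration, blood volume pulse, hand grip force)
    acquired during manual fascial therapy. Implements anti-aliasing FIR
    resampling and Gaussian smoothing, convex-optimization decomposition of
    skin conductance into tonic and phasic components with a Bateman-kernel
    driver, a deep 1-D Morlet wavelet scattering transform, framewise
    feature extraction (scattering-layer energies, spectral entropy,
    time-domain and derivative statistics, an STFT-energy variant),
    double-threshold labeling of sparse 0-10 self-reports, and AdaBoost /
    Gaussian-kernel SVM classification evaluated with balanced 10-fold and
    one-patient-out cross-validation. A synthetic-cohort simulator with
    known ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    rpart,
    e1071,
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
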