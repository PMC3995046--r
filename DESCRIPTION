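Package: erpkit
Title: Event-Related Potential Processing from Event Codes to Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable toolkit for event-related potential (ERP) analysis of
    multichannel EEG recordings. Sorts event codes into averaging bins with a
    bin-descriptor mini-language (sequence matching with latency windows and
    reaction-time capture), extracts and baseline-corrects epochs, flags
    artifacts with detectors tailored to artifact morphology (moving-window
    peak-to-peak, step-like cross-covariance, amplifier blocking, sample-to-
    sample jumps), re-references and recombines channels and bins through a
    small equation language, applies zero-phase Butterworth and windowed-sinc
    filters specified by their half-amplitude cutoff and roll-off, averages
    with artifact-handling modes, builds grand averages and leave-one-out
    jackknife sets, and quantifies amplitudes and latencies (mean and area
    amplitude, local peaks, fractional-area and fractional-peak latency). A
    seeded oddball simulator with known ground truth supports end-to-end
    validation, and plain-text interchange formats are provided for event
    lists and averaged waveforms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
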