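Package: snnHFO
Title: Spiking Neural Network Detection of Fast-Ripple HFOs in Intraoperative ECoG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects fast-ripple high-frequency oscillations (HFOs, 250-500 Hz)
    in multichannel electrocorticography with a simulated spiking neural
    network. The pipeline band-pass filters each channel, estimates a baseline
    amplitude, converts the signal to UP/DN spike trains with an analog
    delta-modulator emulation, and feeds the trains to a two-layer
    integrate-and-fire network whose dis-inhibitory artifact-rejection stage
    suppresses sharp transients while letting genuine oscillations through.
    Second-layer spikes are aggregated into HFO events and per-channel rates;
    residual post-resection HFO rates predict postsurgical seizure outcome
    with exact binomial confidence intervals. A synthetic-data module
    generates ground-truthed recordings so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
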