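Package: peakyabr
Title: Auditory Brainstem Responses to Continuous Peaky Speech and Randomized Click Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving auditory brainstem responses (ABRs) from
    electroencephalography recorded during continuous speech and randomized
    click-train stimulation. Implements glottal-pulse-train ("peaky") speech
    re-synthesis with fundamental-frequency shifting, Poisson click-train
    design with counter-phased epochs, regressor-based frequency-domain
    cross-correlation and deconvolution with inverse-variance weighted
    averaging, a forward model of wave I/III/V generation from an auditory
    periphery simulation, wave V peak picking, and split-half null waveform
    correlation statistics. A seeded synthetic-data module generates speech,
    pulse trains and multi-subject EEG with known ground truth so the whole
    chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    rlang,
    tibble,
    dplyr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
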