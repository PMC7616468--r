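Package: rembeta
Title: Basal Ganglia Beta Oscillations and REM Sleep Atonia Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An analysis pipeline linking basal ganglia local field
    potential (LFP) beta oscillations to loss of REM-sleep muscle atonia.
    Provides hypnogram preparation (scorer consensus, isolated-epoch
    dropping, REM-NREM epoch matching), detection of REM sleep without
    atonia (RSWA) from chin EMG via an individualized integrated-EMG
    threshold, normalized LFP power spectra with beta-burst statistics
    and LFP-EEG coherence, and LFP-beta to EMG envelope connectivity
    with AR(2) whitening, block-shuffle surrogate inference, lagged
    cross-correlation and time-domain Granger directionality.  A
    synthetic polysomnography generator with known ground truth makes
    every stage testable end to end, including EDF export and import.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
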