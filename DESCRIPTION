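Package: seegforce
Title: Grasp-Force State Decoding from Stereo-EEG Band Power
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing grasp-force experiments recorded with
    stereoelectroencephalography (SEEG) depth electrodes: shaft/region
    common-average referencing, short-time Fourier band-power features on a
    50 ms grid with a Savitzky-Golay local motor potential track,
    event-related desynchronization/synchronization (ERD/ERS) modulation
    statistics per channel and band, and nested cross-validated RBF-SVM
    classification of force versus rest and multi-level force states with
    sequential forward feature selection, permutation chance levels, exact
    binomial tests and Benjamini-Hochberg false discovery rate control.
    Includes a synthetic SEEG generator that plants known band-limited
    modulation into 1/f background noise so the whole pipeline is testable
    without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
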