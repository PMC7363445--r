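Package: ripplelock
Title: Ripple-Locked Hippocampal-Neocortical Spindle Coupling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and connectivity analysis of sleep spindles and
    hippocampal sharp-wave ripples in two-channel sleep EEG. Implements
    RMS-envelope event detection with frequency-profile validation,
    automated artifact rejection, duration-matched ripple-free surrogate
    events, Morlet wavelet time-frequency decomposition with adaptive
    cycle counts, spectral coherence, non-parametric partial directed
    coherence, orthogonalized power correlation and phase locking,
    cluster-based permutation statistics, and a synthetic two-channel
    sleep-EEG generator with ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
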