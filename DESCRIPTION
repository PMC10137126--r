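Package: gatewave
Title: Attention-Gated Timing-Prediction Analysis of Epoched EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of trial-epoched EEG from two-by-three
    modality-attention by timing-prediction within-subject designs.
    Generates synthetic multi-subject epochs with programmable evoked
    components, phase-locked oscillations and 1/f background noise;
    implements FIR low-pass filtering, downsampling and trial
    qualification; computes event-related potential window amplitudes,
    Morlet-wavelet inter-trial coherence (ITC) and event-related spectral
    perturbation (ERSP); and runs the gated repeated-measures testing
    scheme (interaction first, then simple effects or main effects, with
    Bonferroni-corrected pairwise contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
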