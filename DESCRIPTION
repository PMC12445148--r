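Package: multisync
Title: Multiplexed Auditory Synchronization: Stimuli, Synthetic EEG, and
    Phase-Locking Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying neural synchronization to nested timescales of
    an amplitude-modulated auditory target in the presence of melodic or
    spectrally matched noise distractors.  Synthesizes concatenated
    sinusoidally amplitude-modulated (SAM) tone targets with exact
    integer-period token boundaries, rule-based melodic distractors with a
    protected frequency band, and melody-matched noise; assembles behavioral
    blocks with a speeded scoring game and rationalized arcsine unit
    summaries; simulates multichannel EEG containing phase-locked components
    at every paradigm timescale over 1/f background noise; and measures
    frequency-following, envelope-following, envelope-change-following and
    beat responses via phase-locking value spectra with noise floors,
    bootstrap trial-count equalization, polarity-based carrier/envelope
    separation, a correct/incorrect asymmetry index, and a sustained-response
    pipeline built on denoising source separation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
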