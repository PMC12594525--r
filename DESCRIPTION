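Package: rhythmtag
Title: Frequency-Tagged EEG Analysis of Rhythmic Attentional Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual frequency-tagged EEG experiments in
    which an attended target and an ignored distractor flicker at distinct
    rates (here 60/14 Hz and 6 Hz). Provides condition-averaged steady-state
    visual evoked potential (SSVEP) extraction with zero-phase narrowband
    isolation, whole-trial amplitudes, spectra and topographies; moving-window
    and Hilbert amplitude-envelope time series with spectral peak detection in
    the delta band; subset-averaged linear-SVM decoding of distractor category
    (pairwise, three-way, moving-window) with label-permutation nulls;
    relative-phase analysis between target- and distractor-processing time
    series; cohort-level circular, uniformity, correlation and ANOVA
    statistics; and a synthetic-EEG generator with known ground truth
    (tagged components, occipital topographies, delta-band amplitude
    modulation, 1/f noise, behavior linked to relative phase) for validation
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'decoding.R'
    'dsp-internals.R'
    'envelope.R'
    'groupstats.R'
    'paradigm.R'
    'phase.R'
    'pipeline.R'
    'rhythmtag-package.R'
    'show-methods.R'
    'simulate.R'
    'ssvep.R'
    'subject-io.R'
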