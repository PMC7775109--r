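Package: rhythmtag
Title: Frequency-Tagged EEG Analysis of Syllable and Word Rhythms in Speech
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for frequency-tagging analysis of cortical responses to
    syllable- and word-rate rhythms in spoken narratives. Provides a synthetic
    stimulus and EEG forward simulator (metrical/nonmetrical syllable
    timelines, isochronous and natural timing, amplitude-modulated
    conditions), a reproducible preprocessing chain (downsampling, mastoid
    re-referencing, linear-phase FIR band-pass filtering with group-delay
    compensation, EOG regression, artifact masking, sentence-aware
    segmentation into fixed-length trials), coherent spectral averaging with
    neighbour-bin peak statistics and circular phase measures, time-warping of
    responses to naturally timed syllables onto an isochronous grid,
    phase-cancellation separation of word-locked and amplitude-modulation
    locked response components, and an inferential layer with BCa bootstrap
    tests, circular confidence intervals, phase-coherence tests, FDR
    correction, cluster-based permutation tests on event-related potentials,
    and paired effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Electrophysiology, TimeCourse, Preprocessing, StatisticalMethod
RoxygenNote: 7.3.3
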