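Package: pupilperm
Title: Pupillometry Preprocessing and Permutation Statistics for
    Interrupted Auditory Attention Experiments
Version: 0.1.0
Authors@R:
    person("pupilperm", "maintainers", email = "pupilperm@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis pipeline for interrupted, reverberant
    auditory spatial-attention pupillometry experiments: prospective power
    analysis and counterbalanced trial/block design, event-kernel synthetic
    pupil and serial-recall data generation, pupil preprocessing (blink
    interpolation, zero-phase Butterworth lowpass filtering, epoching,
    tonic/phasic baseline normalization), serial-recall scoring with
    repeated-measures ANOVA and Bonferroni post-hocs, paired cluster-based
    permutation tests on pupil time courses, sign-flip permutation tests on
    peak latency and amplitude, and room-acoustics utilities (sweep
    deconvolution, Schroeder backward-integration RT60, direct-path
    windowing).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
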