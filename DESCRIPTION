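Package: olfrl
Title: Analysis Toolkit for Olfactory Reward-Learning Experiments in Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the computational chain of a head-fixed mouse
    olfactory reinforcement-learning paradigm with three odor cues rewarded
    at 100, 50 and 0 percent: a trial-based TD(0) model of reward prediction
    and prediction error, estimation of the learning rate from pupillometry,
    lick-based behavioral metrics including a Poisson outcome-history
    regression, spike detection and unit quality control for tetrode
    recordings, population-vector analyses, auROC-based functional unit
    clustering with reward-coding tests, and a miniature event-related BOLD
    GLM with beta-series functional connectivity. A synthetic-data generator
    emulates the task structure, behavior, pupil traces, spike trains, raw
    voltage and BOLD series so that every stage is testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    RNifti
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
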