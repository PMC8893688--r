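Package: teatask
Title: Task-Model Simulation and Crossover-Trial Analysis for Tea-Making
    Rehabilitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the activity of daily living "make a cup of tea" as a
    Markov decision process over eight sub-actions, classifies action-stream
    violations into a ten-category neuropsychological error taxonomy
    (recoverable vs non-recoverable), and runs single trials under an
    assistive cueing policy (help-button, inactivity-timeout and error cues;
    termination on non-recoverable errors or three successive cues) or in
    feedback-free assessment mode.  A synthetic participant and cohort
    simulator reproduces the structure of a two-group crossover
    rehabilitation trial with four assessments, and the statistics layer
    scores assessments, builds within-participant change-score contrasts and
    runs the trial's repeated-measures ANOVAs with Mauchly's sphericity test
    and Greenhouse-Geisser correction, chained-equation imputation,
    inter-rater reliability, exploratory logistic models and sample-size
    planning.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
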