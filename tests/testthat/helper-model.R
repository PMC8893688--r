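# Shared fixtures built in code: one bundled model for the whole suite.
TEST_MODEL <- tea_task_model()

# A perfect scripted stream for a recipe: canonical order, fixed waits.
perfect_stream <- function(rec, wait = 5, boil = 40) {
  steps <- data.frame(subaction = c(canonical_sequence(rec), "done"),
                      wait = wait, stringsAsFactors = FALSE)
  steps$duration <- ifelse(steps$subaction == "boil-water", boil, 0)
  steps
}

zero_profile <- function(...) {
  participant_profile(
    propensities = stats::setNames(rep(0, 10), error_categories()$code),
    timeout_prob = 0, ...)
}
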