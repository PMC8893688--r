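test_that("a perfect performance completes with no cues and no errors", {
  for (nm in c("BT", "WTS")) {
    r <- recipe(nm)
    tr <- run_training_trial(scripted_behaviour(perfect_stream(r)),
                             TEST_MODEL, r)
    expect_equal(tr$outcome, "completed")
    expect_equal(nrow(tr$cues), 0)
    expect_equal(nrow(tr$errors), 0)
    expect_equal(tr$boil_time, 40)
    expect_gte(tr$completion_time_raw, tr$boil_time)
  }
})

test_that("inactivity beyond 30 s triggers a timeout cue recommending the
           most probable next step", {
  steps <- data.frame(subaction = c("add-water-to-kettle", "done"),
                      wait = c(35, 2))
  tr <- run_training_trial(scripted_behaviour(steps), TEST_MODEL,
                           recipe("BT"))
  expect_equal(tr$cues$reason[1], "timeout")
  expect_equal(tr$cues$t[1], 30)
  expect_equal(tr$cues$recommended[1],
               most_probable_next_action(empty_state(), recipe("BT"),
                                         TEST_MODEL))
  # the action at 35 s still executed and reset the cue counter
  expect_equal(tr$events$subaction[1], "add-water-to-kettle")
})

test_that("the inactivity clock is suspended while the kettle boils", {
  r <- recipe("BT")
  steps <- data.frame(
    subaction = c("add-water-to-kettle", "boil-water", "add-teabag",
                  "add-boiled-water", "remove-teabag", "done"),
    wait = c(2, 2, 25, 2, 2, 2),
    duration = c(0, 60, 0, 0, 0, 0))
  # 25 s gap after a 60 s boil: no cue (timer restarted at boil end)
  tr <- run_training_trial(scripted_behaviour(steps), TEST_MODEL, r)
  expect_equal(nrow(tr$cues), 0)
  expect_equal(tr$outcome, "completed")
  # 35 s gap after the boil: cue fires 30 s after boiling ends
  steps$wait[3] <- 35
  tr2 <- run_training_trial(scripted_behaviour(steps), TEST_MODEL, r)
  expect_equal(tr2$cues$reason[1], "timeout")
  expect_equal(tr2$cues$t[1], 2 + 2 + 60 + 30)
})

test_that("a non-recoverable error terminates with the error type reported", {
  steps <- data.frame(
    subaction = c("add-water-to-kettle", "boil-water", "add-teabag",
                  "add-boiled-water", "add-sugar"),
    wait = 3)
  tr <- run_training_trial(scripted_behaviour(steps), TEST_MODEL,
                           recipe("WT"))
  expect_equal(tr$outcome, "terminated_nonrecoverable")
  expect_match(tr$termination_message, "^N-ADD")
  expect_match(tr$termination_message, "sugar not required")
  # no events processed after the terminal outcome
  expect_equal(tr$events$subaction[nrow(tr$events)], "add-sugar")
  expect_equal(nrow(tr$events), 5)
})

test_that("three successive ignored cues end the trial at exactly the third", {
  steps <- data.frame(subaction = c("add-water-to-kettle", "boil-water"),
                      wait = c(3, 200))
  tr <- run_training_trial(scripted_behaviour(steps), TEST_MODEL,
                           recipe("BT"))
  expect_equal(tr$outcome, "terminated_3cues")
  # hand simulation: action at 3 s, cues at 33, 63, 93
  expect_equal(tr$cues$t, c(33, 63, 93))
  expect_equal(nrow(tr$cues), 3)
  # the stalled action never executed
  expect_equal(nrow(tr$events), 1)
})

test_that("the cue counter resets on a correct action between cues", {
  # two long stalls (one cue each) separated by correct actions: no
  # termination because the cues are never successive
  steps <- data.frame(
    subaction = c("add-water-to-kettle", "boil-water", "add-teabag",
                  "add-boiled-water", "remove-teabag", "done"),
    wait = c(35, 35, 35, 3, 3, 2))
  tr <- run_training_trial(scripted_behaviour(steps), TEST_MODEL,
                           recipe("BT"))
  expect_equal(tr$outcome, "completed")
  expect_equal(nrow(tr$cues), 3)
  expect_true(all(tr$cues$reason == "timeout"))
})

test_that("recoverable errors cue immediately; omissions are cued at task end", {
  # a sequence error mid-trial draws an error cue
  steps <- data.frame(
    subaction = c("add-water-to-kettle", "boil-water", "add-teabag",
                  "remove-teabag", "add-boiled-water", "done"),
    wait = 3)
  tr <- run_training_trial(scripted_behaviour(steps), TEST_MODEL,
                           recipe("BT"))
  expect_true("error" %in% tr$cues$reason)
  expect_equal(tr$errors$code[1], "R-SEQ")
  # omission: scripted completion without milk draws an end-of-task cue
  r <- recipe("WT")
  steps2 <- data.frame(
    subaction = c("add-water-to-kettle", "boil-water", "add-teabag",
                  "add-boiled-water", "remove-teabag", "done"),
    wait = 3)
  tr2 <- run_training_trial(scripted_behaviour(steps2), TEST_MODEL, r)
  expect_true("R-SOM" %in% tr2$errors$code)
  last_cues <- tr2$cues[tr2$cues$reason == "error", ]
  expect_true(all(last_cues$recommended == "add-milk"))
  # scripted stream never complies, so the trial ends on successive cues
  expect_equal(tr2$outcome, "terminated_3cues")
})

test_that("cue recommendations are always permitted at the firing state", {
  p <- participant_profile(timeout_prob = 0.3, cue_compliance = 0.5)
  set.seed(11)
  for (i in 1:20) {
    r <- tea_recipes()[[sample(4, 1)]]
    beh <- simulate_behaviour(p, r, mode = "training")
    tr <- run_training_trial(beh, TEST_MODEL, r)
    if (nrow(tr$cues) == 0) next
    # replay up to each cue time and check the recommendation
    for (j in seq_len(nrow(tr$cues))) {
      tc <- tr$cues$t[j]
      rec <- tr$cues$recommended[j]
      if (is.na(rec)) next
      done <- tr$events[tr$events$t + tr$events$duration <= tc + 1e-9, ]
      st <- replay_state(lapply(seq_len(nrow(done)), function(k)
        action_event(done$subaction[k], duration = done$duration[k],
                     quantity = done$quantity[k])))
      expect_true(rec %in% permitted_next_actions(st, r),
                  info = sprintf("cue %d (%s) in trial %d", j, rec, i))
    }
  }
})

test_that("assessment mode never cues or terminates and appends omissions", {
  r <- recipe("WTS")
  steps <- data.frame(
    subaction = c("add-water-to-kettle", "boil-water", "add-teabag",
                  "add-boiled-water", "add-sugar", "remove-teabag", "done"),
    wait = 4)
  tr <- run_assessment_trial(scripted_behaviour(steps), TEST_MODEL, r)
  expect_equal(tr$outcome, "completed")
  expect_equal(nrow(tr$cues), 0)
  # milk omitted, stir omitted after sugar: one R-SOM each, plus the
  # addition error for WT is absent here (sugar is required for WTS)
  expect_equal(sort(tr$errors$subaction[tr$errors$code == "R-SOM"]),
               c("add-milk", "stir"))
  # even a non-recoverable error does not end an assessment trial
  steps2 <- data.frame(
    subaction = c("add-water-to-kettle", "boil-water", "add-teabag",
                  "add-boiled-water", "add-sugar", "add-milk",
                  "remove-teabag", "done"),
    wait = 4)
  tr2 <- run_assessment_trial(scripted_behaviour(steps2), TEST_MODEL,
                              recipe("WT"))
  expect_equal(tr2$outcome, "completed")
  expect_true("N-ADD" %in% tr2$errors$code)
  expect_equal(nrow(tr2$events), 7)
})

test_that("training and assessment agree on an error-free stream", {
  r <- recipe("BTS")
  steps <- perfect_stream(r)
  tr_t <- run_training_trial(scripted_behaviour(steps), TEST_MODEL, r)
  tr_a <- run_assessment_trial(scripted_behaviour(steps), TEST_MODEL, r)
  tr_t$mode <- tr_a$mode
  expect_identical(tr_t, tr_a)
})

test_that("boil time is deducted correctly from scripted timings", {
  r <- recipe("BT")
  steps <- perfect_stream(r, wait = 10, boil = 55)
  tr <- run_assessment_trial(scripted_behaviour(steps), TEST_MODEL, r)
  # 6 waits of 10 s plus the 55 s boil
  expect_equal(tr$completion_time_raw, 60 + 55)
  expect_equal(tr$boil_time, 55)
  expect_equal(tr$completion_time_raw - tr$boil_time, 60)
})

test_that("malformed behaviour streams are rejected with a position", {
  bad <- list(next_step = function(ctx) list(type = "dance", wait = 1),
              on_cue = function(cue, ctx, pending) NULL)
  expect_error(run_assessment_trial(bad, TEST_MODEL, recipe("BT")),
               "malformed behaviour stream at position 1")
})

test_that("session composition yields two of each tea type, reproducibly", {
  s1 <- compose_session(3, 2, seed = 99)
  s2 <- compose_session(3, 2, seed = 99)
  expect_identical(s1, s2)
  counts <- table(s1$recipe)
  expect_setequal(names(counts), c("BT", "BTS", "WT", "WTS"))
  expect_true(all(counts == 2))
  expect_equal(which(s1$break_after), c(4L, 8L))
  # different sessions shuffle differently (almost surely)
  orders <- vapply(1:50, function(s)
    paste(compose_session(1, 1, seed = s)$recipe, collapse = ""),
    character(1))
  expect_gt(length(unique(orders)), 10)
  # first-position frequency is uniform over seeds
  first <- vapply(1:1000, function(s)
    compose_session(1, 1, seed = s)$recipe[1], character(1))
  freqs <- table(first) / 1000
  expect_true(all(abs(freqs - 0.25) < 0.04))
})
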