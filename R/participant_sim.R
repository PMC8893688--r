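#' Default per-opportunity error propensities
#'
#' Baseline probabilities, per opportunity, that a simulated participant
#' with apraxia/action-disorganisation commits each category of error.
#' The profile mirrors the observed error mix: kettle-operation errors are
#' the most common non-recoverable category and continuous perseveration
#' the most common recoverable one before training.
#'
#' @return Named numeric vector over the 10 category codes.
#' @export
default_propensities <- function() {
  c("N-ADD" = 0.04, "N-OSUB" = 0.03, "N-KET" = 0.10, "N-QMO" = 0.02,
    "R-CP" = 0.12, "R-EX" = 0.05, "R-RP" = 0.06, "R-SEQ" = 0.05,
    "R-QMU" = 0.06, "R-SOM" = 0.05)
}

#' Create a synthetic participant profile
#'
#' @param id Participant identifier.
#' @param group Crossover group (1 starts with tea training, 2 with the
#'   stepping control).
#' @param age Years.
#' @param sex `"F"` or `"M"`.
#' @param years_post_stroke Years since the stroke.
#' @param propensities Named per-opportunity error probabilities (see
#'   [default_propensities()]).
#' @param timeout_prob Probability, per step, of a stall longer than the
#'   30-s inactivity timeout.
#' @param cue_compliance Probability of following a cue when one is shown.
#' @param base_step_time_mean,base_step_time_sd Per-step completion time
#'   model (seconds; normal, truncated at 0.5 s).
#' @param boil_time_mean,boil_time_sd Kettle boil duration model (seconds;
#'   normal, truncated at 20 s).
#' @param training_effect Fractional reduction of recoverable-error
#'   propensities (and step time) after tea-making training; 0 = none.
#' @param time_reduction_s Seconds by which the per-trial completion time
#'   falls after training (spread over the steps of a trial).
#' @param retention Fraction of the training effect retained at follow-up.
#' @return An object of class `"participant_profile"`.
#' @export
participant_profile <- function(id = 1L, group = 1L, age = 71, sex = "F",
                                years_post_stroke = 4.6,
                                propensities = default_propensities(),
                                timeout_prob = 0.05,
                                cue_compliance = 0.8,
                                base_step_time_mean = 8,
                                base_step_time_sd = 2,
                                boil_time_mean = 45,
                                boil_time_sd = 8,
                                training_effect = 0.5,
                                time_reduction_s = 15,
                                retention = 1.0) {
  cats <- error_categories()$code
  if (!all(cats %in% names(propensities))) {
    stop("propensities must name all 10 error categories")
  }
  p <- propensities[cats]
  stopifnot(all(p >= 0 & p <= 1), timeout_prob >= 0, timeout_prob <= 1,
            cue_compliance >= 0, cue_compliance <= 1,
            training_effect >= 0, training_effect <= 1,
            retention >= 0, retention <= 1, age > 0)
  structure(list(id = id, group = group, age = age, sex = sex,
                 years_post_stroke = years_post_stroke,
                 propensities = p, timeout_prob = timeout_prob,
                 cue_compliance = cue_compliance,
                 base_step_time_mean = base_step_time_mean,
                 base_step_time_sd = base_step_time_sd,
                 boil_time_mean = boil_time_mean,
                 boil_time_sd = boil_time_sd,
                 training_effect = training_effect,
                 time_reduction_s = time_reduction_s,
                 retention = retention),
            class = "participant_profile")
}

#' Randomly allocate participants to the two crossover groups
#'
#' Seeded permutation with equal numbers per group (sizes differ by at
#' most 1 when `n` is odd).
#'
#' @param n Number of participants (at least 2).
#' @param seed Integer seed.
#' @return Integer vector of group labels (1 or 2), one per participant id
#'   `1..n`.
#' @export
allocate_groups <- function(n, seed = 1L) {
  if (n < 2) stop("need at least 2 participants to allocate groups")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  labels <- rep(c(1L, 2L), c(ceiling(n / 2), floor(n / 2)))
  sample(labels)
}

# Build the planned event script for one trial: the canonical sequence
# perturbed by sampled error injections.  Injections are insertions,
# annotations or (for omissions) deletions chosen so that no injection
# creates knock-on errors at later steps; per-category counts therefore
# have exact, linear expectations in the propensities (see the methods
# vignette).  Uses the current RNG state.
plan_trial <- function(profile, recipe, multiplier = 1, step_time_delta = 0) {
  p <- profile$propensities
  p[c("R-CP", "R-EX", "R-RP", "R-SEQ", "R-QMU", "R-SOM")] <-
    p[c("R-CP", "R-EX", "R-RP", "R-SEQ", "R-QMU", "R-SOM")] * multiplier
  req <- recipe$required
  has_sugar <- recipe$requires_sugar
  has_milk <- recipe$requires_milk

  drop_sugar <- has_sugar && stats::runif(1) < p["R-SOM"]
  drop_milk <- has_milk && stats::runif(1) < p["R-SOM"]
  early_remove <- stats::runif(1) < p["R-SEQ"]
  refill <- stats::runif(1) < p["R-RP"]
  early_boil <- stats::runif(1) < p["N-KET"]
  coffee <- stats::runif(1) < p["N-OSUB"]
  extra_sugar <- !has_sugar && stats::runif(1) < p["N-ADD"]
  extra_milk <- !has_milk && stats::runif(1) < p["N-ADD"]
  long_stir <- has_sugar && stats::runif(1) < p["R-CP"]
  underfill <- stats::runif(1) < p["R-QMU"]
  overfill <- !underfill && stats::runif(1) < p["N-QMO"]
  clumsy <- stats::runif(3) < p["R-EX"]   # fill, boil, teabag

  qty <- if (underfill) 0.4 else if (overfill) 1.2 else 1
  rows <- list()
  add <- function(sub, duration = 0, quantity = NA_real_, flag = FALSE) {
    rows[[length(rows) + 1L]] <<- list(subaction = sub, duration = duration,
                                       quantity = quantity,
                                       execution_flag = flag)
  }
  if (early_boil) add("boil-water")
  add("add-water-to-kettle", flag = clumsy[1])
  if (refill) add("add-water-to-kettle")
  boil_dur <- max(20, stats::rnorm(1, profile$boil_time_mean,
                                   profile$boil_time_sd))
  add("boil-water", duration = boil_dur, flag = clumsy[2])
  if (coffee) add("add-coffee")
  add("add-teabag", flag = clumsy[3])
  if (early_remove) add("remove-teabag")
  add("add-boiled-water", quantity = qty)
  if (has_sugar && !drop_sugar) add("add-sugar")
  if (has_milk && !drop_milk) add("add-milk")
  if (extra_sugar) add("add-sugar")
  if (extra_milk) add("add-milk")
  if (has_sugar) add("stir", duration = if (long_stir) 12 else 2)
  if (!early_remove) add("remove-teabag")

  n <- length(rows)
  stall <- stats::runif(n) < profile$timeout_prob
  mu <- max(0.5, profile$base_step_time_mean - step_time_delta)
  waits <- pmax(0.5, stats::rnorm(n, mu, profile$base_step_time_sd))
  waits[stall] <- 40
  for (k in seq_len(n)) rows[[k]]$wait <- waits[k]
  rows[[n + 1L]] <- list(subaction = "done", duration = 0,
                         quantity = NA_real_, execution_flag = FALSE,
                         wait = max(0.5, stats::rnorm(1, 2, 0.5)))
  rows
}

#' Simulate a participant's behaviour stream for one trial
#'
#' Emits the canonical permitted sequence for the recipe, perturbed by
#' sampled errors (one Bernoulli draw per category per opportunity),
#' stalls, and — in training mode — cue responses governed by the
#' profile's cue compliance.  The stream is reproducible from the RNG
#' state at the time of the call.
#'
#' @param profile A [participant_profile()].
#' @param recipe A [recipe()].
#' @param mode `"training"` or `"assessment"` (affects only cue handling,
#'   which the engine drives).
#' @param multiplier Multiplicative factor applied to the recoverable-error
#'   propensities (1 = baseline; `1 - training_effect` after training).
#' @param step_time_delta Seconds subtracted from the mean step time
#'   (training speed-up).
#' @return A behaviour object for the trial engines.
#' @export
simulate_behaviour <- function(profile, recipe, mode = "assessment",
                               multiplier = 1, step_time_delta = 0) {
  queue <- plan_trial(profile, recipe, multiplier, step_time_delta)
  pop <- function() {
    if (length(queue) == 0L) return(NULL)
    head <- queue[[1L]]
    queue <<- queue[-1L]
    head
  }
  list(
    next_step = function(ctx) {
      row <- pop()
      if (is.null(row)) return(NULL)
      if (row$subaction == "done") {
        list(type = "done", wait = row$wait)
      } else {
        list(type = "action", subaction = row$subaction, wait = row$wait,
             duration = row$duration, quantity = row$quantity,
             execution_flag = row$execution_flag)
      }
    },
    on_cue = function(cue, ctx, pending) {
      if (is.na(cue$recommended)) return(NULL)
      if (stats::runif(1) >= profile$cue_compliance) return(NULL)
      rec <- cue$recommended
      # consume the recommended step from the remaining plan (or the
      # pending intent) so compliance does not duplicate it later
      if (!is.null(pending) && identical(pending$subaction, rec)) {
        dur <- if (is.null(pending$duration)) 0 else pending$duration
        qty <- if (is.null(pending$quantity)) NA_real_ else pending$quantity
      } else {
        if (!is.null(pending)) queue <<- c(list(pending), queue)
        hit <- which(vapply(queue, function(r)
          identical(r$subaction, rec), logical(1)))
        if (length(hit) > 0L) {
          dur <- queue[[hit[1L]]]$duration
          qty <- queue[[hit[1L]]]$quantity
          queue <<- queue[-hit[1L]]
        } else {
          dur <- if (rec == "boil-water")
            max(20, stats::rnorm(1, profile$boil_time_mean,
                                 profile$boil_time_sd))
          else if (rec == "stir") 2 else 0
          qty <- if (rec == "add-boiled-water") 1 else NA_real_
        }
      }
      list(type = "action", subaction = rec,
           wait = max(0.5, stats::rnorm(1, 3, 0.5)),
           duration = dur, quantity = qty, execution_flag = FALSE)
    }
  )
}

#' Exact expected per-trial error counts under the behaviour model
#'
#' Closed-form expectation of the number of classified errors per category
#' for one assessment-mode trial of a recipe, given a profile.  The
#' generator's injection rules are designed so these expectations are
#' exact and linear in the propensities (the only coupling is that a
#' quantity-overestimation draw is suppressed when the underestimation
#' draw fires on the same water event).
#'
#' @inheritParams simulate_behaviour
#' @return Named numeric vector over the 10 category codes.
#' @export
expected_error_counts <- function(profile, recipe, multiplier = 1) {
  p <- profile$propensities
  rec_codes <- c("R-CP", "R-EX", "R-RP", "R-SEQ", "R-QMU", "R-SOM")
  p[rec_codes] <- p[rec_codes] * multiplier
  n_drop <- sum(c("add-sugar", "add-milk") %in% recipe$required)
  n_extra <- 2 - n_drop
  c("N-ADD" = unname(p["N-ADD"]) * n_extra,
    "N-OSUB" = unname(p["N-OSUB"]),
    "N-KET" = unname(p["N-KET"]),
    "N-QMO" = unname(p["N-QMO"]) * (1 - unname(p["R-QMU"])),
    "R-CP" = unname(p["R-CP"]) * as.numeric(recipe$requires_sugar),
    "R-EX" = unname(p["R-EX"]) * 3,
    "R-RP" = unname(p["R-RP"]),
    "R-SEQ" = unname(p["R-SEQ"]),
    "R-QMU" = unname(p["R-QMU"]),
    "R-SOM" = unname(p["R-SOM"]) * n_drop)
}

#' Configure a synthetic crossover cohort
#'
#' Defaults reproduce the structure of the trial being emulated: 15
#' participants per group, four assessments (baseline, post-phase-1,
#' post-phase-2, follow-up), Group 1 trains tea making in Phase 1 and
#' Group 2 in Phase 2, five one-hour training sessions per phase, a
#' roughly 10% dropout rate, and a training effect that halves the
#' recoverable-error propensities and removes about 15 s from the trial
#' completion time, fully retained at follow-up.
#'
#' @param n_per_group Participants per group.
#' @param seed Integer seed; the whole cohort is a pure function of
#'   (config, seed).
#' @param age_mean,age_sd,prop_female,years_mean,years_sd Baseline
#'   characteristic distributions.
#' @param propensities,timeout_prob,cue_compliance,base_step_time_mean,base_step_time_sd
#'   Passed to [participant_profile()].
#' @param training_effect,time_reduction_s,retention Effect structure (see
#'   [participant_profile()]).
#' @param dropout_prob Probability that a participant drops out during the
#'   trial (losing all assessments from a random point after baseline).
#' @param simulate_training_sessions Also run the five tea-training
#'   sessions of each participant's training phase through the
#'   training-mode engine (adds realism and cue/termination data but not
#'   scored outcomes; off by default to keep large simulation studies
#'   cheap).
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_per_group = 15, seed = 1L,
                          age_mean = 71.1, age_sd = 7.8,
                          prop_female = 0.44,
                          years_mean = 4.6, years_sd = 3.3,
                          propensities = default_propensities(),
                          timeout_prob = 0.05, cue_compliance = 0.8,
                          base_step_time_mean = 8, base_step_time_sd = 2,
                          training_effect = 0.5, time_reduction_s = 15,
                          retention = 1.0, dropout_prob = 0.1,
                          simulate_training_sessions = FALSE) {
  stopifnot(n_per_group >= 1, dropout_prob >= 0, dropout_prob <= 1)
  structure(as.list(environment()), class = "cohort_config")
}

# multiplier and step-time delta for (group, assessment) under the
# crossover schedule: Group 1 trains tea in Phase 1 (effect from
# assessment 2), Group 2 in Phase 2 (effect from assessment 3); the
# follow-up assessment (4) carries the retention-modulated effect.
phase_effect <- function(group, assessment, effect, retention) {
  trained <- if (group == 1L) assessment >= 2 else assessment >= 3
  if (!trained) return(0)
  if (assessment == 4L) effect * retention else effect
}

#' Simulate a full crossover cohort
#'
#' Generates profiles, allocates groups, runs 4 assessments x 8
#' assessment-mode trials per participant (plus, optionally, the five
#' training sessions of the tea phase in training mode), applies the
#' training effect according to each group's phase order, and scores every
#' assessment.  Fully reproducible from `(config, seed)`.
#'
#' @param config A [cohort_config()].
#' @param model A task model from [tea_task_model()].
#' @param keep_trials Keep the raw `"trial_record"`s (memory-heavy for
#'   simulation studies; scores are always kept).
#' @return A list with `config`, `baseline` (one row per participant),
#'   `scores` (long data.frame: participant, group, assessment,
#'   recoverable, nonrecoverable, mean_time; NA rows for missed
#'   assessments), `trials` (list or NULL) and `training_trials`.
#' @export
simulate_cohort <- function(config, model = tea_task_model(),
                            keep_trials = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  n <- 2L * config$n_per_group
  groups <- allocate_groups(n, seed = config$seed)
  set.seed(as.integer(config$seed))

  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    profiles[[i]] <- participant_profile(
      id = i, group = groups[i],
      age = round(max(40, min(95, stats::rnorm(1, config$age_mean,
                                               config$age_sd)))),
      sex = if (stats::runif(1) < config$prop_female) "F" else "M",
      years_post_stroke = round(max(0.5, stats::rnorm(1, config$years_mean,
                                                      config$years_sd)), 1),
      propensities = config$propensities,
      timeout_prob = config$timeout_prob,
      cue_compliance = config$cue_compliance,
      base_step_time_mean = config$base_step_time_mean,
      base_step_time_sd = config$base_step_time_sd,
      training_effect = config$training_effect,
      time_reduction_s = config$time_reduction_s,
      retention = config$retention)
  }
  dropout_at <- rep(NA_integer_, n)
  drops <- stats::runif(n) < config$dropout_prob
  dropout_at[drops] <- sample(2:4, sum(drops), replace = TRUE)

  baseline <- data.frame(
    participant = seq_len(n), group = groups,
    age = vapply(profiles, `[[`, numeric(1), "age"),
    sex = vapply(profiles, `[[`, character(1), "sex"),
    years_post_stroke = vapply(profiles, `[[`, numeric(1),
                               "years_post_stroke"),
    dropout_at = dropout_at,
    stringsAsFactors = FALSE)

  scores <- vector("list", n * 4L)
  trials <- if (keep_trials) list() else NULL
  training_trials <- if (keep_trials) list() else NULL

  for (i in seq_len(n)) {
    prof <- profiles[[i]]
    for (a in 1:4) {
      row_id <- (i - 1L) * 4L + a
      if (!is.na(dropout_at[i]) && a >= dropout_at[i]) {
        scores[[row_id]] <- data.frame(
          participant = i, group = groups[i], assessment = a,
          recoverable = NA_real_, nonrecoverable = NA_real_,
          mean_time = NA_real_)
        next
      }
      eff <- phase_effect(groups[i], a, prof$training_effect, prof$retention)
      mult <- 1 - eff
      delta <- (eff / max(prof$training_effect, 1e-12)) *
        prof$time_reduction_s / 7
      if (prof$training_effect == 0) delta <- 0
      session <- compose_session(i, a, seed = config$seed)
      trs <- vector("list", 8L)
      for (k in 1:8) {
        beh <- simulate_behaviour(prof, model$recipes[[session$recipe[k]]],
                                  mode = "assessment", multiplier = mult,
                                  step_time_delta = delta)
        trs[[k]] <- run_assessment_trial(beh, model,
                                         model$recipes[[session$recipe[k]]],
                                         participant_id = i,
                                         trial_id = sprintf("a%d.%d", a, k))
      }
      sc <- score_assessment(trs)
      scores[[row_id]] <- data.frame(
        participant = i, group = groups[i], assessment = a,
        recoverable = sc$recoverable_errors,
        nonrecoverable = sc$nonrecoverable_errors,
        mean_time = sc$mean_time)
      if (keep_trials) trials <- c(trials, trs)
    }
    if (config$simulate_training_sessions) {
      tea_phase_sessions <- 5L
      for (s in seq_len(tea_phase_sessions)) {
        session <- compose_session(i, 100L + s, seed = config$seed)
        for (k in 1:8) {
          beh <- simulate_behaviour(prof,
                                    model$recipes[[session$recipe[k]]],
                                    mode = "training", multiplier = 1,
                                    step_time_delta = 0)
          tr <- run_training_trial(beh, model,
                                   model$recipes[[session$recipe[k]]],
                                   participant_id = i,
                                   trial_id = sprintf("t%d.%d", s, k))
          if (keep_trials) training_trials <- c(training_trials, list(tr))
        }
      }
    }
  }
  list(config = config, baseline = baseline,
       scores = do.call(rbind, scores),
       trials = trials, training_trials = training_trials)
}

#' Generate a synthetic baseline-characteristics table
#'
#' Emits a table in the schema of the packaged baseline table (group, age,
#' sex, lesion, handedness before/after stroke, years post stroke, NEADL,
#' Fugl-Meyer, anxiety, depression), drawn from the configured
#' distributions.  Instrument scores are synthetic covariates only.
#'
#' @param config A [cohort_config()].
#' @return A data.frame, one row per participant.
#' @export
generate_baseline_table <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  n <- 2L * config$n_per_group
  groups <- allocate_groups(n, seed = config$seed)
  set.seed(as.integer(config$seed) + 1L)
  data.frame(
    no = seq_len(n),
    group = groups,
    age = round(pmax(40, pmin(95, stats::rnorm(n, config$age_mean,
                                               config$age_sd)))),
    sex = ifelse(stats::runif(n) < config$prop_female, "F", "M"),
    lesion = sample(c("left", "right", "bilat", "unconf"), n, replace = TRUE,
                    prob = c(0.3, 0.35, 0.1, 0.25)),
    hand_pre = sample(c("right", "left"), n, replace = TRUE,
                      prob = c(0.8, 0.2)),
    hand_post = sample(c("right", "left", "both"), n, replace = TRUE,
                       prob = c(0.55, 0.4, 0.05)),
    years_post_stroke = round(pmax(0.5, stats::rnorm(n, config$years_mean,
                                                     config$years_sd)), 1),
    neadl = round(pmax(5, pmin(66, stats::rnorm(n, 38, 12)))),
    fm = round(pmax(0, pmin(20, stats::rnorm(n, 12, 6)))),
    anx = round(pmax(0, pmin(21, stats::rnorm(n, 5, 3)))),
    dep = round(pmax(0, pmin(21, stats::rnorm(n, 6, 4)))),
    stringsAsFactors = FALSE)
}

#' The packaged baseline characteristics table
#'
#' The 25-row baseline table of the analysed cohort (group, age, sex,
#' lesion, handedness before/after stroke, years post stroke, NEADL,
#' Fugl-Meyer, anxiety and depression scores).  Years post stroke is
#' recorded as published: lower-bound bands such as `">5"` for most rows,
#' plain years for the rest; [summarize_baseline()] reads a band as its
#' bound.
#'
#' @return A data.frame with 25 rows.
#' @export
baseline_characteristics <- function() {
  path <- system.file("extdata", "baseline_characteristics.csv",
                      package = "teatask")
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(years_post_stroke = "character"))
}
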