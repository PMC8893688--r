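#' Create an action event
#'
#' One timestamped performed sub-action (or distractor-object use), as
#' entered by the experimenter's action buttons or emitted by the
#' simulator.
#'
#' @param subaction Sub-action id, or a declared distractor such as
#'   `"add-coffee"`.
#' @param t Seconds since trial start at which the action occurred.
#' @param duration Seconds the action took (for `boil-water` this is the
#'   boil time; for `stir` the stirring duration).
#' @param quantity Optional fill fraction or ingredient count (for
#'   `add-boiled-water`, 1 = full cup).
#' @param execution_flag Optional clumsiness annotation: execution-quality
#'   errors are judged from movement quality and cannot be inferred from a
#'   discrete log, so they enter as pre-coded flags.
#' @return An object of class `"action_event"`.
#' @export
action_event <- function(subaction, t = NA_real_, duration = 0,
                         quantity = NA_real_, execution_flag = FALSE) {
  structure(list(subaction = subaction, t = t, duration = duration,
                 quantity = quantity, execution_flag = execution_flag),
            class = "action_event")
}

#' Thresholds used by the error classifier
#'
#' @param stir_cp_threshold_s Continuous stirring beyond this duration is a
#'   continuous-perseveration error (R-CP); 10 s.
#' @param underfill_threshold Cup fill fraction below this is a
#'   quantity-underestimation error (R-QMU); 0.5.
#' @param overfill_threshold Fill fraction above this is a
#'   quantity-overestimation error (N-QMO); no threshold is stated for
#'   overfilling, so the default is a full cup (1.0), configurable.
#' @return A list of thresholds.
#' @export
error_config <- function(stir_cp_threshold_s = 10,
                         underfill_threshold = 0.5,
                         overfill_threshold = 1.0) {
  list(stir_cp_threshold_s = stir_cp_threshold_s,
       underfill_threshold = underfill_threshold,
       overfill_threshold = overfill_threshold)
}

error_event <- function(code, subaction, note = "", step_index = NA_integer_,
                        t = NA_real_) {
  structure(list(code = code, recoverable = is_recoverable(code),
                 subaction = subaction, note = note,
                 step_index = step_index, t = t),
            class = "error_event")
}

#' Classify one performed action against the task model
#'
#' Deterministically maps a (state, event, recipe) triple to `NULL` (the
#' action is a permitted step) or a single error category.  When an event
#' matches several categories the fixed priority order of
#' [error_categories()] applies: non-recoverable first (they terminate the
#' trial), then recoverable, each class in listing order.  Over the
#' discrete vocabulary with default event attributes, the classifier is the
#' exact complement of [permitted_next_actions()].
#'
#' Omissions are not classified here: they are end-of-task judgements made
#' by [detect_omissions()].
#'
#' @param state The `"task_state"` *before* the event.
#' @param event An [action_event()].
#' @param recipe A [recipe()].
#' @param config Thresholds from [error_config()].
#' @return `NULL` if the action is permitted, otherwise an `"error_event"`
#'   with fields `code`, `recoverable`, `subaction`, `note`.
#' @export
classify_event <- function(state, event, recipe, config = error_config()) {
  if (is.character(event)) event <- action_event(event)
  sub <- event$subaction
  if (!sub %in% c(TEA_SUBACTIONS, TEA_DISTRACTORS)) {
    stop("unknown object/sub-action in event: ", sub)
  }
  dur <- if (is.null(event$duration) || is.na(event$duration)) 0 else event$duration
  qty <- event$quantity
  err <- function(code, note) error_event(code, sub, note, t = event$t)

  ## -- non-recoverable ------------------------------------------------
  # N-OSUB: wrong object (coffee instead of tea)
  if (sub %in% TEA_DISTRACTORS) {
    return(err("N-OSUB", "distractor object used"))
  }
  # N-ADD: component action not required by the recipe
  if (sub == "add-sugar" && !recipe$requires_sugar) {
    return(err("N-ADD", "sugar not required"))
  }
  if (sub == "add-milk" && !recipe$requires_milk) {
    return(err("N-ADD", "milk not required"))
  }
  if (sub == "stir" && !recipe$requires_sugar) {
    return(err("N-ADD", "stirring not required for this recipe"))
  }
  # N-KET: kettle not operated correctly
  if (sub == "boil-water" && !state$kettle_filled) {
    return(err("N-KET", "kettle switched on before water added"))
  }
  if (sub == "add-boiled-water" && !state$kettle_boiled) {
    return(err("N-KET", "water used without boiling"))
  }
  # N-QMO: too much of an ingredient
  if (sub == "add-boiled-water" &&
      !is.na(qty) && qty > config$overfill_threshold) {
    return(err("N-QMO", sprintf("cup overfilled (%.0f%%)", 100 * qty)))
  }

  ## -- recoverable ----------------------------------------------------
  # R-CP: continuous perseveration (prolonged stirring)
  if (sub == "stir" && dur > config$stir_cp_threshold_s) {
    return(err("R-CP", sprintf("continuous stirring for %.1f s", dur)))
  }
  # R-EX: annotated clumsy execution
  if (isTRUE(event$execution_flag)) {
    return(err("R-EX", "clumsy execution (annotated)"))
  }
  # R-RP: recurrent perseveration (re-doing an achieved step)
  if (sub == "add-water-to-kettle" && state$kettle_filled) {
    return(err("R-RP", "kettle already filled"))
  }
  if (sub == "boil-water" && state$kettle_boiled) {
    return(err("R-RP", "water already boiled"))
  }
  if (sub == "add-teabag" && (state$teabag_in_cup || state$teabag_removed)) {
    return(err("R-RP", "teabag already used"))
  }
  if (sub == "add-boiled-water" && state$water_in_cup) {
    return(err("R-RP", "water already in cup"))
  }
  if (sub == "add-sugar" && state$sugar_count >= 1L) {
    return(err("R-RP", "sugar already added"))
  }
  if (sub == "add-milk" && state$milk_count >= 1L) {
    return(err("R-RP", "milk already added"))
  }
  if (sub == "stir" && state$water_in_cup && !state$stir_pending) {
    return(err("R-RP", "repeated stirring, nothing new to mix"))
  }
  if (sub == "remove-teabag" && state$teabag_removed) {
    return(err("R-RP", "teabag already removed"))
  }
  # R-SEQ: wrong order
  if (sub == "remove-teabag" && !state$teabag_in_cup) {
    return(err("R-SEQ", "no teabag in cup to remove"))
  }
  if (sub == "remove-teabag" && !state$water_in_cup) {
    return(err("R-SEQ", "teabag removed before adding water"))
  }
  if (sub == "stir" && !state$water_in_cup) {
    return(err("R-SEQ", "stirring before water added"))
  }
  # R-QMU: too little of an ingredient
  if (sub == "add-boiled-water" && !is.na(qty) &&
      qty < config$underfill_threshold) {
    return(err("R-QMU", sprintf("cup only %.0f%% full", 100 * qty)))
  }
  NULL
}

#' Detect step omissions at end of task
#'
#' Called when the participant signals completion (or activity ceases):
#' every required-but-unachieved sub-action yields one step-omission
#' (R-SOM) error.
#'
#' @param final_state The `"task_state"` at end of task.
#' @param recipe A [recipe()].
#' @return List of `"error_event"`s (empty at the goal state).
#' @export
detect_omissions <- function(final_state, recipe) {
  missing <- setdiff(recipe$required, achieved_set(final_state))
  lapply(missing, function(a) {
    error_event("R-SOM", a, sprintf("required step '%s' omitted", a))
  })
}

#' Tally classified errors in a trial
#'
#' @param trial A `"trial_record"` (see [run_assessment_trial()]), or any
#'   list with an `errors` data.frame bearing a `code` column.
#' @return Named list: `by_category` (named integer vector over all 10
#'   codes), `recoverable`, `nonrecoverable` and `total` counts.
#' @export
tally_errors <- function(trial) {
  cats <- ERROR_CATS
  codes <- if (is.data.frame(trial$errors)) trial$errors$code else
    vapply(trial$errors, function(e) e$code, character(1))
  by_cat <- stats::setNames(tabulate(match(codes, cats$code), nrow(cats)),
                            cats$code)
  rec <- sum(by_cat[cats$recoverable])
  nonrec <- sum(by_cat[!cats$recoverable])
  list(by_category = by_cat, recoverable = rec, nonrecoverable = nonrec,
       total = rec + nonrec)
}
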