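#' Cueing-policy parameters
#'
#' @param timeout_s Inactivity timeout: a cue fires when more than this many
#'   seconds elapse since the previous action (default 30).  The inactivity
#'   clock is suspended while the kettle boils and restarts, with the full
#'   timeout, when boiling ends.
#' @param max_successive_cues Number of successive cues (no intervening
#'   correct action) after which the trial is terminated (default 3).
#' @return A list of policy parameters.
#' @export
policy_params <- function(timeout_s = 30, max_successive_cues = 3) {
  list(timeout_s = timeout_s, max_successive_cues = max_successive_cues)
}

#' Wrap a scripted event table as a behaviour stream
#'
#' A behaviour stream is the engine-facing model of a participant: a list
#' with `next_step(ctx)` returning the next intended event and an optional
#' `on_cue(cue, ctx, pending)` hook for cue responses.  A scripted
#' behaviour replays a fixed table and ignores all cues — the shape of the
#' data produced by a human coder pressing action buttons.
#'
#' @param steps A data.frame with columns `subaction` (a sub-action id,
#'   `"help"` for a help-button press, or `"done"` to signal completion),
#'   `wait` (seconds since the previous activity), and optionally
#'   `duration`, `quantity`, `execution_flag`.
#' @return A behaviour object for [run_training_trial()] /
#'   [run_assessment_trial()].
#' @export
scripted_behaviour <- function(steps) {
  if (!is.data.frame(steps) || !all(c("subaction", "wait") %in% names(steps))) {
    stop("scripted behaviour needs a data.frame with 'subaction' and 'wait'")
  }
  if (is.null(steps$duration)) steps$duration <- 0
  if (is.null(steps$quantity)) steps$quantity <- NA_real_
  if (is.null(steps$execution_flag)) steps$execution_flag <- FALSE
  i <- 0L
  list(
    next_step = function(ctx) {
      i <<- i + 1L
      if (i > nrow(steps)) return(NULL)
      row <- steps[i, ]
      if (row$subaction == "done") {
        list(type = "done", wait = row$wait)
      } else if (row$subaction == "help") {
        list(type = "help", wait = row$wait)
      } else {
        list(type = "action", subaction = row$subaction, wait = row$wait,
             duration = row$duration, quantity = row$quantity,
             execution_flag = isTRUE(row$execution_flag))
      }
    },
    on_cue = function(cue, ctx, pending) NULL
  )
}

new_cue <- function(t, reason, recommended) {
  list(t = t, reason = reason, recommended = recommended)
}

# minimal-overhead data.frame constructor for the trial hot path
fast_df <- function(cols) {
  n <- length(cols[[1L]])
  structure(cols, class = "data.frame", row.names = c(NA_integer_, -n))
}

#' Run one training trial under the cueing policy
#'
#' Consumes a behaviour stream and applies the training-mode policy: a
#' multimodal cue is displayed (1) when the participant presses the
#' help/repeat button, (2) when more than `timeout_s` elapse since the
#' previous action (clock suspended while the kettle boils), or (3) when
#' the participant makes a recoverable error; the cue recommends the most
#' probable permitted next step.  Omission errors are cued at the end of
#' the task.  A non-recoverable error ends the trial immediately with the
#' error type reported; three successive cues with no intervening correct
#' action also end the trial.  The successive-cue counter resets on any
#' correct action.
#'
#' @param behaviour A behaviour stream (see [scripted_behaviour()] or
#'   [simulate_behaviour()]).
#' @param model A `"task_model"` from [tea_task_model()].
#' @param recipe A [recipe()].
#' @param policy Policy parameters from [policy_params()].
#' @param participant_id,trial_id Identifiers copied into the record.
#' @return A `"trial_record"`: list with `events`, `cues`, `errors`
#'   data.frames, `outcome` (`"completed"`, `"terminated_nonrecoverable"`
#'   or `"terminated_3cues"`), `completion_time_raw`, `boil_time`,
#'   `termination_message` and identifiers.
#' @export
run_training_trial <- function(behaviour, model, recipe,
                               policy = policy_params(),
                               participant_id = NA, trial_id = NA) {
  run_trial(behaviour, model, recipe, mode = "training", policy = policy,
            participant_id = participant_id, trial_id = trial_id)
}

#' Run one assessment trial (no feedback)
#'
#' Assessment mode mirrors the assessed tea tasks: no cues are ever
#' emitted, no time limit applies, self-correction is permitted (later
#' corrective actions simply occur; each error is still counted once), and
#' the trial ends when the stream signals completion or ceases.  Omissions
#' are appended at the end by [detect_omissions()].  Assessment trials
#' never terminate early.
#'
#' @inheritParams run_training_trial
#' @return A `"trial_record"`; `outcome` is always `"completed"`.
#' @export
run_assessment_trial <- function(behaviour, model, recipe,
                                 participant_id = NA, trial_id = NA) {
  run_trial(behaviour, model, recipe, mode = "assessment",
            policy = policy_params(), participant_id = participant_id,
            trial_id = trial_id)
}

run_trial <- function(behaviour, model, recipe, mode, policy,
                      participant_id, trial_id) {
  training <- mode == "training"
  state <- empty_state()
  t_now <- 0; timer_ref <- 0
  successive <- 0L
  boil_time <- 0
  ev <- list(t = numeric(), subaction = character(), duration = numeric(),
             quantity = numeric(), execution_flag = logical())
  cues <- list(t = numeric(), reason = character(), recommended = character())
  errs <- list(step_index = integer(), t = numeric(), code = character(),
               recoverable = logical(), subaction = character(),
               note = character())
  outcome <- NULL; term_msg <- NA_character_
  n_steps <- 0L

  push_cue <- function(reason, recommended, t) {
    cues$t <<- c(cues$t, t)
    cues$reason <<- c(cues$reason, reason)
    cues$recommended <<- c(cues$recommended, recommended)
  }
  push_err <- function(e, step_index = NA_integer_, t = NA_real_) {
    errs$step_index <<- c(errs$step_index, step_index)
    errs$t <<- c(errs$t, t)
    errs$code <<- c(errs$code, e$code)
    errs$recoverable <<- c(errs$recoverable, e$recoverable)
    errs$subaction <<- c(errs$subaction, e$subaction)
    errs$note <<- c(errs$note, e$note)
  }
  recommend <- function() {
    perm <- permitted_next_actions(state, recipe, model)
    if (length(perm) == 0L) NA_character_ else
      most_probable_next_action(state, recipe, model)
  }
  ctx <- function() list(state = state, recipe = recipe, t = t_now,
                         mode = mode)
  check_intent <- function(intent, pos) {
    if (!is.list(intent) || is.null(intent$type) ||
        !intent$type %in% c("action", "help", "done") ||
        is.null(intent$wait) || is.na(intent$wait) || intent$wait < 0 ||
        (intent$type == "action" && is.null(intent$subaction))) {
      stop("malformed behaviour stream at position ", pos)
    }
  }

  pending <- NULL
  repeat {
    if (n_steps > 1000L) stop("behaviour stream did not terminate")
    if (is.null(pending)) {
      pending <- behaviour$next_step(ctx())
      n_steps <- n_steps + 1L
      if (!is.null(pending)) check_intent(pending, n_steps)
    }
    if (is.null(pending)) {
      # stream ceased: assessment ends; training stalls into timeout cues
      if (!training) { outcome <- "ceased"; break }
      repeat {
        t_cue <- timer_ref + policy$timeout_s
        cue <- new_cue(t_cue, "timeout", recommend())
        push_cue(cue$reason, cue$recommended, t_cue)
        timer_ref <- t_cue; t_now <- t_cue
        successive <- successive + 1L
        if (successive >= policy$max_successive_cues) {
          outcome <- "terminated_3cues"; break
        }
        resp <- behaviour$on_cue(cue, ctx(), NULL)
        if (!is.null(resp)) { pending <- resp; break }
      }
      if (!is.null(outcome)) break
      next
    }

    t_act <- t_now + pending$wait

    if (training) {
      # inactivity cues fire while the intended act lies beyond the timeout
      while (t_act > timer_ref + policy$timeout_s) {
        t_cue <- timer_ref + policy$timeout_s
        cue <- new_cue(t_cue, "timeout", recommend())
        push_cue(cue$reason, cue$recommended, t_cue)
        successive <- successive + 1L
        timer_ref <- t_cue
        if (successive >= policy$max_successive_cues) {
          outcome <- "terminated_3cues"; t_now <- t_cue; break
        }
        resp <- behaviour$on_cue(cue, ctx(), pending)
        if (!is.null(resp)) {
          check_intent(resp, n_steps)
          pending <- resp
          t_act <- t_cue + resp$wait
        }
      }
      if (!is.null(outcome)) break
    }

    if (pending$type == "done") { t_now <- t_act; outcome <- "done"; break }

    if (pending$type == "help") {
      t_now <- t_act
      if (training) {
        cue <- new_cue(t_act, "help_button", recommend())
        push_cue(cue$reason, cue$recommended, t_act)
        successive <- successive + 1L
        timer_ref <- t_act
        if (successive >= policy$max_successive_cues) {
          outcome <- "terminated_3cues"; break
        }
        pending <- behaviour$on_cue(cue, ctx(), NULL)
      } else pending <- NULL
      next
    }

    # an action event
    event <- action_event(pending$subaction, t = t_act,
                          duration = if (is.null(pending$duration)) 0 else pending$duration,
                          quantity = if (is.null(pending$quantity)) NA_real_ else pending$quantity,
                          execution_flag = isTRUE(pending$execution_flag))
    pending <- NULL
    cls <- classify_event(state, event, recipe)
    ev$t <- c(ev$t, t_act)
    ev$subaction <- c(ev$subaction, event$subaction)
    ev$duration <- c(ev$duration, event$duration)
    ev$quantity <- c(ev$quantity, event$quantity)
    ev$execution_flag <- c(ev$execution_flag, event$execution_flag)
    idx <- length(ev$t)
    state <- advance_state(state, event)
    t_now <- t_act + event$duration
    if (event$subaction == "boil-water" && is.null(cls)) {
      boil_time <- boil_time + event$duration
    }
    if (is.null(cls)) {
      successive <- 0L
      timer_ref <- t_now
    } else {
      push_err(cls, idx, t_act)
      if (!cls$recoverable) {
        state$nonrecoverable <- TRUE
        if (training) {
          outcome <- "terminated_nonrecoverable"
          term_msg <- sprintf("%s: %s", cls$code, cls$note)
          break
        }
      } else if (training) {
        timer_ref <- t_now
        cue <- new_cue(t_now, "error", recommend())
        push_cue(cue$reason, cue$recommended, t_now)
        successive <- successive + 1L
        if (successive >= policy$max_successive_cues) {
          outcome <- "terminated_3cues"; break
        }
        pending <- behaviour$on_cue(cue, ctx(), NULL)
      } else {
        timer_ref <- t_now
      }
    }
  }

  # end-of-task handling
  if (outcome %in% c("done", "ceased")) {
    if (!training) {
      for (om in detect_omissions(state, recipe)) push_err(om, t = t_now)
      outcome <- "completed"
    } else {
      cued_omissions <- character()
      repeat {
        oms <- detect_omissions(state, recipe)
        if (length(oms) == 0L) { outcome <- "completed"; break }
        om_subs <- vapply(oms, function(o) o$subaction, character(1))
        for (k in seq_along(oms)) {
          if (!om_subs[k] %in% cued_omissions) {
            push_err(oms[[k]], t = t_now)
            cued_omissions <- c(cued_omissions, om_subs[k])
          }
        }
        perm <- permitted_next_actions(state, recipe, model)
        target <- intersect(om_subs, perm)
        rec <- if (length(target) > 0L) target[1] else recommend()
        cue <- new_cue(t_now, "error", rec)
        push_cue(cue$reason, cue$recommended, t_now)
        successive <- successive + 1L
        timer_ref <- t_now
        if (successive >= policy$max_successive_cues) {
          outcome <- "terminated_3cues"; break
        }
        resp <- behaviour$on_cue(cue, ctx(), NULL)
        if (is.null(resp)) {
          t_now <- t_now + policy$timeout_s
        } else {
          check_intent(resp, n_steps)
          if (resp$type == "action") {
            t_act <- t_now + resp$wait
            event <- action_event(resp$subaction, t = t_act,
                                  duration = if (is.null(resp$duration)) 0 else resp$duration,
                                  quantity = if (is.null(resp$quantity)) NA_real_ else resp$quantity)
            cls <- classify_event(state, event, recipe)
            ev$t <- c(ev$t, t_act)
            ev$subaction <- c(ev$subaction, event$subaction)
            ev$duration <- c(ev$duration, event$duration)
            ev$quantity <- c(ev$quantity, event$quantity)
            ev$execution_flag <- c(ev$execution_flag, FALSE)
            state <- advance_state(state, event)
            t_now <- t_act + event$duration
            if (is.null(cls)) { successive <- 0L } else {
              push_err(cls, length(ev$t), t_act)
              if (!cls$recoverable) {
                state$nonrecoverable <- TRUE
                outcome <- "terminated_nonrecoverable"
                term_msg <- sprintf("%s: %s", cls$code, cls$note)
                break
              }
            }
          }
        }
      }
    }
  }

  structure(list(
    participant_id = participant_id, trial_id = trial_id,
    recipe = recipe$name, mode = mode,
    events = fast_df(ev),
    cues = fast_df(cues),
    errors = fast_df(errs),
    outcome = outcome,
    termination_message = term_msg,
    completion_time_raw = t_now,
    boil_time = boil_time
  ), class = "trial_record")
}

#' Compose the eight-cup session order
#'
#' Each assessment (and each training session) comprises 8 cups of tea, two
#' of each type, in an order randomized per participant and session; breaks
#' follow trials 4 and 8.
#'
#' @param participant_id,session_index Combined with `seed` to derive the
#'   per-session shuffling seed, so each participant and session gets a
#'   distinct but reproducible order.
#' @param seed Base integer seed.
#' @return A data.frame with columns `position` (1..8), `recipe` and
#'   `break_after`.
#' @export
compose_session <- function(participant_id = 1L, session_index = 1L,
                            seed = 1L) {
  stopifnot(is.numeric(seed))
  local_seed <- as.integer((as.numeric(seed) * 1009 +
                            as.numeric(participant_id) * 97 +
                            as.numeric(session_index)) %% 2147483647)
  # save/restore the global RNG state so session composition is a pure
  # function of (participant, session, seed)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(local_seed)
  recs <- sample(rep(c("BT", "BTS", "WT", "WTS"), 2))
  data.frame(position = 1:8, recipe = recs,
             break_after = (1:8) %in% c(4L, 8L),
             stringsAsFactors = FALSE)
}
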