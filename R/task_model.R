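#' @title MDP task model of tea making
#' @description
#' Tea making is modelled as a Markov decision process: the state is the set
#' of sub-actions achieved so far, transitions are the permitted next
#' sub-actions, and transition probabilities are estimated from sequences
#' produced by healthy control participants.  Errors are violations of the
#' permitted transitions; the most probable permitted successor is what the
#' cueing policy recommends.
#' @name task_model
NULL

TEA_SUBACTIONS <- c("add-water-to-kettle", "boil-water", "add-teabag",
                    "add-boiled-water", "add-sugar", "add-milk",
                    "stir", "remove-teabag")

# Declared distractor objects: usable in an event stream, never permitted.
TEA_DISTRACTORS <- c("add-coffee")

#' The eight tea-making sub-actions
#'
#' @return A data.frame with columns `id` and `description`.
#' @export
tea_subactions <- function() {
  data.frame(
    id = TEA_SUBACTIONS,
    description = c("add water from jug to kettle", "boil water",
                    "add teabag to cup", "add boiled water to cup",
                    "add sugar to cup", "add milk to cup", "stir",
                    "remove teabag"),
    stringsAsFactors = FALSE
  )
}

#' Define a tea recipe
#'
#' The four assessed tea types are black tea (BT), black tea with sugar
#' (BTS), white tea i.e. with milk (WT) and white tea with sugar (WTS).  The
#' required sub-action set is derived from the two ingredient flags: every
#' recipe requires filling and boiling the kettle, adding a teabag, adding
#' boiled water and removing the teabag; sugar recipes additionally require
#' adding sugar and stirring (to dissolve it), milk recipes require adding
#' milk.  Stirring is required only when sugar is present and teabag removal
#' is always required; both conventions are configurable at the call sites
#' that consume `required`.
#'
#' @param name One of `"BT"`, `"BTS"`, `"WT"`, `"WTS"`, or any label when
#'   the two flags are given explicitly.
#' @param requires_milk,requires_sugar Ingredient flags; defaulted from
#'   `name` for the four standard types.
#' @return An object of class `"recipe"`: a list with `name`,
#'   `requires_milk`, `requires_sugar` and `required` (character vector of
#'   required sub-action ids).
#' @examples
#' recipe("WTS")$required
#' @export
recipe <- function(name, requires_milk = NULL, requires_sugar = NULL) {
  std <- list(BT = c(FALSE, FALSE), BTS = c(FALSE, TRUE),
              WT = c(TRUE, FALSE), WTS = c(TRUE, TRUE))
  if (is.null(requires_milk) || is.null(requires_sugar)) {
    if (!name %in% names(std)) {
      stop("unknown recipe '", name,
           "'; give requires_milk/requires_sugar explicitly")
    }
    requires_milk <- std[[name]][1]
    requires_sugar <- std[[name]][2]
  }
  required <- c("add-water-to-kettle", "boil-water", "add-teabag",
                "add-boiled-water",
                if (requires_sugar) "add-sugar",
                if (requires_milk) "add-milk",
                if (requires_sugar) "stir",
                "remove-teabag")
  structure(list(name = name, requires_milk = requires_milk,
                 requires_sugar = requires_sugar, required = required),
            class = "recipe")
}

#' The four bundled recipes
#' @return Named list of [recipe()] objects `BT`, `BTS`, `WT`, `WTS`.
#' @export
tea_recipes <- function() {
  r <- lapply(c("BT", "BTS", "WT", "WTS"), recipe)
  names(r) <- c("BT", "BTS", "WT", "WTS")
  r
}

#' Create an empty task state
#'
#' A task state is a pure function of the sequence of performed events:
#' replaying the same events always reproduces the same flags (see
#' [replay_state()]).
#'
#' @return An object of class `"task_state"`.
#' @export
empty_state <- function() {
  structure(list(
    completed = character(),       # performed sub-actions, in order
    kettle_filled = FALSE,
    kettle_boiled = FALSE,
    water_in_cup = FALSE,
    cup_fill_fraction = 0,
    teabag_in_cup = FALSE,
    teabag_removed = FALSE,
    milk_count = 0L,
    sugar_count = 0L,
    stir_count = 0L,
    stir_pending = FALSE,          # a mixable ingredient arrived since last stir
    stir_total_duration = 0,
    nonrecoverable = FALSE
  ), class = "task_state")
}

#' Advance a task state by one performed event
#'
#' Updates the derived flags for a performed sub-action.  Physically
#' ineffective actions leave the flags unchanged: boiling an empty kettle
#' boils nothing, stirring an empty cup mixes nothing, a distractor object
#' changes nothing.  The event is always appended to `completed`.
#'
#' @param state A `"task_state"`.
#' @param event An [action_event()] (or a bare sub-action id).
#' @return The updated state.
#' @export
advance_state <- function(state, event) {
  if (is.character(event)) event <- action_event(event)
  sub <- event$subaction
  dur <- if (is.null(event$duration) || is.na(event$duration)) 0 else event$duration
  qty <- event$quantity
  switch(sub,
    "add-water-to-kettle" = { state$kettle_filled <- TRUE },
    "boil-water" = { if (state$kettle_filled) state$kettle_boiled <- TRUE },
    "add-teabag" = { state$teabag_in_cup <- TRUE },
    "add-boiled-water" = {
      state$water_in_cup <- TRUE
      state$cup_fill_fraction <- if (is.null(qty) || is.na(qty)) 1 else qty
      state$stir_pending <- TRUE
    },
    "add-sugar" = { state$sugar_count <- state$sugar_count + 1L
                    state$stir_pending <- TRUE },
    "add-milk" = { state$milk_count <- state$milk_count + 1L
                   state$stir_pending <- TRUE },
    "stir" = { if (state$water_in_cup) {
                 state$stir_count <- state$stir_count + 1L
                 state$stir_pending <- FALSE
                 state$stir_total_duration <- state$stir_total_duration + dur
               } },
    "remove-teabag" = { if (state$teabag_in_cup) {
                          state$teabag_in_cup <- FALSE
                          state$teabag_removed <- TRUE
                        } },
    { if (!sub %in% TEA_DISTRACTORS) stop("unknown sub-action: ", sub) }
  )
  state$completed <- c(state$completed, sub)
  state
}

#' Replay a sequence of events into a task state
#'
#' @param events A list of [action_event()]s or a character vector of
#'   sub-action ids.
#' @param recipe Optional [recipe()]; when given, each event is classified
#'   as it is replayed and the state's `nonrecoverable` flag is set if any
#'   non-recoverable error occurs.
#' @return A `"task_state"`.
#' @export
replay_state <- function(events, recipe = NULL) {
  state <- empty_state()
  if (is.character(events)) events <- lapply(events, action_event)
  for (ev in events) {
    if (!is.null(recipe)) {
      err <- classify_event(state, ev, recipe)
      if (!is.null(err) && !err$recoverable) state$nonrecoverable <- TRUE
    }
    state <- advance_state(state, ev)
  }
  state
}

# The set of *achieved* sub-actions implied by a state's flags; this (not
# the raw event order) is the conditioning context of the transition table.
achieved_set <- function(state) {
  c(if (state$kettle_filled) "add-water-to-kettle",
    if (state$kettle_boiled) "boil-water",
    if (state$teabag_in_cup || state$teabag_removed) "add-teabag",
    if (state$water_in_cup) "add-boiled-water",
    if (state$sugar_count > 0L) "add-sugar",
    if (state$milk_count > 0L) "add-milk",
    if (state$stir_count > 0L) "stir",
    if (state$teabag_removed) "remove-teabag")
}

# Context keys are parenthesised so the empty context has a usable name.
context_key <- function(achieved) {
  paste0("(", paste(sort(achieved), collapse = "|"), ")")
}

#' Permitted next sub-actions
#'
#' Returns exactly the sub-actions whose preconditions hold in `state` and
#' whose execution would not constitute any taxonomy error for `recipe`.
#' The rules are explicit preconditions (e.g. the kettle cannot be boiled
#' before it is filled); [classify_event()] is their exact complement over
#' the discrete action vocabulary, a property the test suite checks by
#' exhaustive enumeration.
#'
#' @param state A `"task_state"`.
#' @param recipe A [recipe()].
#' @param model Optional task model (unused by the bundled rules, accepted
#'   for signature stability with alternative models).
#' @return Character vector of permitted sub-action ids (possibly empty,
#'   e.g. at the goal state).
#' @export
permitted_next_actions <- function(state, recipe, model = NULL) {
  ok <- c(
    "add-water-to-kettle" = !state$kettle_filled,
    "boil-water" = state$kettle_filled && !state$kettle_boiled,
    "add-teabag" = !state$teabag_in_cup && !state$teabag_removed,
    "add-boiled-water" = state$kettle_boiled && !state$water_in_cup,
    "add-sugar" = recipe$requires_sugar && state$sugar_count < 1L,
    "add-milk" = recipe$requires_milk && state$milk_count < 1L,
    "stir" = recipe$requires_sugar && state$water_in_cup && state$stir_pending,
    "remove-teabag" = state$teabag_in_cup && state$water_in_cup
  )
  names(ok)[ok]
}

#' Has the task reached its goal?
#'
#' True iff every required sub-action of the recipe has been achieved and no
#' non-recoverable error has occurred (the latter is tracked when the state
#' is replayed or advanced under a recipe-aware caller).
#'
#' @param state A `"task_state"`.
#' @param recipe A [recipe()].
#' @return Logical flag.
#' @export
is_goal <- function(state, recipe) {
  all(recipe$required %in% achieved_set(state)) && !isTRUE(state$nonrecoverable)
}

#' Estimate a transition table from control sequences
#'
#' State-transition probabilities are estimated from complete task
#' performances (typically by healthy controls).  The conditioning context
#' is the unordered set of sub-actions achieved so far.  With observed
#' counts `n(c, a)` and a per-cell pseudocount `q`, the probability of
#' successor `a` in context `c` is `(n(c,a) + q) / (N(c) + K*q)` where
#' `K` is the number of candidate successors at `c`.  A positive
#' pseudocount (default 0.5, Jeffreys-style) keeps unseen-but-candidate
#' successors cueable.
#'
#' @param sequences List of character vectors, each a complete sub-action
#'   sequence, or a data.frame with columns `sequence_id`, `step_index`,
#'   `subaction_id` (the control-sequence CSV layout).
#' @param pseudocount Non-negative smoothing count added per candidate.
#' @param vocabulary Known sub-action ids; defaults to the tea vocabulary.
#' @param candidates Optional function(context character vector) returning
#'   the candidate successor set at that context; defaults to the successors
#'   observed in the data at that context.
#' @return An object of class `"transition_table"`: a named list mapping a
#'   context key (sorted achieved set joined by `"|"`) to a named
#'   probability vector over candidate successors; each row sums to 1.
#' @examples
#' tt <- estimate_transitions(list(c("A", "B", "C"), c("A", "C", "B")),
#'                            pseudocount = 0, vocabulary = c("A", "B", "C"))
#' tt[["(A)"]]  # P(B) = P(C) = 0.5 after A
#' @export
estimate_transitions <- function(sequences, pseudocount = 0.5,
                                 vocabulary = TEA_SUBACTIONS,
                                 candidates = NULL) {
  if (is.data.frame(sequences)) {
    need <- c("sequence_id", "step_index", "subaction_id")
    if (!all(need %in% names(sequences))) {
      stop("control-sequence table must have columns ",
           paste(need, collapse = ", "))
    }
    sequences <- sequences[order(sequences$sequence_id, sequences$step_index), ]
    sequences <- split(sequences$subaction_id, sequences$sequence_id)
  }
  if (length(sequences) == 0L) stop("no sequences supplied")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  bad <- setdiff(unique(unlist(sequences)), vocabulary)
  if (length(bad) > 0L) {
    stop("unknown sub-action id(s) in sequences: ", paste(bad, collapse = ", "))
  }
  counts <- list()
  contexts <- list()
  for (seq in sequences) {
    achieved <- character()
    for (a in seq) {
      key <- context_key(achieved)
      cnt <- counts[[key]]
      cnt[a] <- if (is.null(cnt) || is.na(cnt[a])) 1 else cnt[a] + 1
      counts[[key]] <- cnt
      contexts[[key]] <- achieved
      achieved <- union(achieved, a)
    }
  }
  tab <- lapply(names(counts), function(key) {
    cnt <- counts[[key]]
    cand <- if (is.null(candidates)) names(cnt) else candidates(contexts[[key]])
    cand <- sort(union(cand, names(cnt)))
    full <- stats::setNames(rep(0, length(cand)), cand)
    full[names(cnt)] <- cnt
    (full + pseudocount) / (sum(full) + length(cand) * pseudocount)
  })
  names(tab) <- names(counts)
  structure(tab, class = "transition_table", pseudocount = pseudocount)
}

#' Most probable permitted next sub-action
#'
#' The cue recommendation: among the sub-actions permitted at `state` for
#' `recipe`, the one with the highest estimated transition probability.
#' Ties (and contexts absent from the table, where the distribution is
#' taken as uniform) are broken by lexicographic order of sub-action id,
#' for reproducibility.
#'
#' @inheritParams permitted_next_actions
#' @param model A `"task_model"` (see [tea_task_model()]).
#' @return A single sub-action id.
#' @export
most_probable_next_action <- function(state, recipe, model) {
  perm <- permitted_next_actions(state, recipe, model)
  if (length(perm) == 0L) stop("task complete: no permitted next action")
  perm <- sort(perm)
  probs <- model$transitions[[context_key(achieved_set(state))]]
  p <- if (is.null(probs)) stats::setNames(rep(1, length(perm)), perm) else {
    v <- probs[perm]
    v[is.na(v)] <- 0
    stats::setNames(as.numeric(v), perm)
  }
  perm[which.max(p)]  # which.max takes the first (lexicographic) maximum
}

#' Synthetic healthy-control tea-making sequences
#'
#' The transition probabilities of the bundled model are estimated from
#' control performances.  No such corpus is published, so the package ships
#' a synthetic, deterministic stand-in: for each recipe, the canonical
#' ordering (kettle first, teabag before water, sugar before milk, stir
#' after all soluble ingredients, teabag out last) is repeated with weight
#' 6, and permitted variants (teabag before boiling; milk/sugar order
#' swapped; milk after teabag removal) appear with weight 1 each, mimicking
#' the dominant-path-plus-minority-variants structure of healthy
#' performance.
#'
#' @return A named list of character vectors (names carry the recipe and
#'   variant).
#' @export
control_sequences <- function() {
  canon <- list(
    BT  = c("add-water-to-kettle", "boil-water", "add-teabag",
            "add-boiled-water", "remove-teabag"),
    BTS = c("add-water-to-kettle", "boil-water", "add-teabag",
            "add-boiled-water", "add-sugar", "stir", "remove-teabag"),
    WT  = c("add-water-to-kettle", "boil-water", "add-teabag",
            "add-boiled-water", "add-milk", "remove-teabag"),
    WTS = c("add-water-to-kettle", "boil-water", "add-teabag",
            "add-boiled-water", "add-sugar", "add-milk", "stir",
            "remove-teabag")
  )
  variants <- list(
    # teabag dropped in while the kettle heats
    BT2  = c("add-water-to-kettle", "add-teabag", "boil-water",
             "add-boiled-water", "remove-teabag"),
    BTS2 = c("add-water-to-kettle", "add-teabag", "boil-water",
             "add-boiled-water", "add-sugar", "stir", "remove-teabag"),
    WT2  = c("add-water-to-kettle", "add-teabag", "boil-water",
             "add-boiled-water", "remove-teabag", "add-milk"),
    # milk before sugar / milk last
    WTS2 = c("add-water-to-kettle", "boil-water", "add-teabag",
             "add-boiled-water", "add-milk", "add-sugar", "stir",
             "remove-teabag"),
    WTS3 = c("add-water-to-kettle", "add-teabag", "boil-water",
             "add-boiled-water", "add-sugar", "stir", "remove-teabag",
             "add-milk")
  )
  out <- c(rep(canon, each = 6), variants)
  nm <- c(paste0(rep(names(canon), each = 6), ".", rep(1:6, 4)),
          names(variants))
  names(out) <- nm
  out
}

#' The bundled tea-making task model
#'
#' Assembles the sub-action vocabulary, the four recipes, the permission
#' rules and a transition table estimated from [control_sequences()] (or
#' sequences you supply).  Candidate successors at each context are the
#' union of permitted next actions over the four recipes, so a positive
#' pseudocount makes every permitted-but-unseen continuation cueable.
#'
#' @param sequences Control sequences for [estimate_transitions()];
#'   defaults to the bundled synthetic set.
#' @param pseudocount Smoothing count, default 0.5.
#' @return An object of class `"task_model"`.
#' @export
tea_task_model <- function(sequences = control_sequences(),
                           pseudocount = 0.5) {
  recipes <- tea_recipes()
  cand_fn <- function(achieved) {
    st <- state_from_achieved(achieved)
    sort(unique(unlist(lapply(recipes, function(r)
      permitted_next_actions(st, r)))))
  }
  structure(list(
    subactions = tea_subactions(),
    recipes = recipes,
    transitions = estimate_transitions(sequences, pseudocount,
                                       candidates = cand_fn),
    pseudocount = pseudocount,
    version = "1.0"
  ), class = "task_model")
}

# Reconstruct a state whose flags correspond to an achieved set (used when
# interpreting transition-table contexts, which forget event order).  A
# canonical permitted order is replayed when one exists; otherwise flags are
# set directly.
state_from_achieved <- function(achieved) {
  st <- empty_state()
  st$kettle_filled <- "add-water-to-kettle" %in% achieved
  st$kettle_boiled <- "boil-water" %in% achieved
  st$water_in_cup <- "add-boiled-water" %in% achieved
  st$cup_fill_fraction <- if (st$water_in_cup) 1 else 0
  st$teabag_removed <- "remove-teabag" %in% achieved
  st$teabag_in_cup <- ("add-teabag" %in% achieved) && !st$teabag_removed
  st$sugar_count <- as.integer("add-sugar" %in% achieved)
  st$milk_count <- as.integer("add-milk" %in% achieved)
  st$stir_count <- as.integer("stir" %in% achieved)
  # stirring is pending if a mixable ingredient is present and no stir has
  # happened yet (order information is lost; this is the convention used
  # for context interpretation)
  st$stir_pending <- st$water_in_cup && st$stir_count == 0L
  st$completed <- achieved
  st
}

#' Canonical permitted sequence for a recipe
#'
#' @param recipe A [recipe()].
#' @return Character vector of sub-action ids reaching the goal.
#' @export
canonical_sequence <- function(recipe) {
  c("add-water-to-kettle", "boil-water", "add-teabag", "add-boiled-water",
    if (recipe$requires_sugar) "add-sugar",
    if (recipe$requires_milk) "add-milk",
    if (recipe$requires_sugar) "stir",
    "remove-teabag")
}

#' Enumerate all permitted goal-reaching sequences
#'
#' Exhaustive depth-first search over the permitted transition graph from
#' the empty state, up to `max_steps` steps.  Used to verify that each
#' recipe admits several distinct correct orderings (the premise that a
#' single fixed sequence cannot accommodate personal choice, e.g. milk
#' before or after water).
#'
#' @param recipe A [recipe()].
#' @param max_steps Search depth, default 8 (the longest recipe).
#' @return List of character vectors, each a permitted goal sequence.
#' @export
enumerate_goal_sequences <- function(recipe, max_steps = 8) {
  out <- list()
  recurse <- function(state, seq) {
    if (is_goal(state, recipe)) {
      out[[length(out) + 1L]] <<- seq
      return(invisible())
    }
    if (length(seq) >= max_steps) return(invisible())
    for (a in permitted_next_actions(state, recipe)) {
      recurse(advance_state(state, a), c(seq, a))
    }
  }
  recurse(empty_state(), character())
  out
}
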