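#' Write a task model to JSON
#'
#' Serialises the vocabulary, recipes and transition table with a schema
#' `version` field.  Permission rules are part of the schema semantics
#' (they are predicates, not data) and are re-attached on read.
#'
#' @param model A `"task_model"`.
#' @param path Output file.
#' @export
write_task_model <- function(model, path) {
  obj <- list(
    schema = "teatask/task-model",
    version = model$version,
    pseudocount = model$pseudocount,
    subactions = model$subactions,
    recipes = lapply(model$recipes, function(r)
      list(name = r$name, requires_milk = r$requires_milk,
           requires_sugar = r$requires_sugar, required = r$required)),
    transitions = lapply(unclass(model$transitions), as.list)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a task model from JSON
#'
#' @param path A file written by [write_task_model()].
#' @return A `"task_model"`.
#' @export
read_task_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$schema) || obj$schema != "teatask/task-model") {
    stop("not a task-model file (missing schema tag): ", path)
  }
  if (is.null(obj$version)) stop("task-model file lacks a version field")
  trans <- lapply(obj$transitions, function(row) unlist(row))
  recipes <- lapply(obj$recipes, function(r)
    recipe(r$name, requires_milk = r$requires_milk,
           requires_sugar = r$requires_sugar))
  names(recipes) <- vapply(recipes, `[[`, character(1), "name")
  sub <- do.call(rbind, lapply(obj$subactions, function(s)
    data.frame(id = s$id, description = s$description,
               stringsAsFactors = FALSE)))
  structure(list(subactions = sub, recipes = recipes,
                 transitions = structure(trans, class = "transition_table",
                                         pseudocount = obj$pseudocount),
                 pseudocount = obj$pseudocount, version = obj$version),
            class = "task_model")
}

#' Write trial records as JSON lines
#'
#' One JSON object per record with a `record_type` discriminator
#' (`trial`, then nested events/cues/errors); deterministic field order
#' for diff-ability.
#'
#' @param trials A `"trial_record"` or list of them.
#' @param path Output file.
#' @export
write_trial_log <- function(trials, path) {
  if (inherits(trials, "trial_record")) trials <- list(trials)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (tr in trials) {
    obj <- list(record_type = "trial",
                participant_id = tr$participant_id,
                trial_id = tr$trial_id, recipe = tr$recipe,
                mode = tr$mode, outcome = tr$outcome,
                termination_message = tr$termination_message,
                completion_time_raw = tr$completion_time_raw,
                boil_time = tr$boil_time,
                events = tr$events, cues = tr$cues, errors = tr$errors)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                na = "null", dataframe = "rows"), con)
  }
  invisible(path)
}

#' Read a trial log written by [write_trial_log()]
#'
#' @param path JSONL file.
#' @return List of `"trial_record"`s.
#' @export
read_trial_log <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e)
                      stop("malformed trial log at line ", i, ": ",
                           conditionMessage(e)))
    if (is.null(obj$record_type) || obj$record_type != "trial") {
      stop("unexpected record_type at line ", i)
    }
    as_df <- function(x, cols) {
      if (is.null(x) || length(x) == 0) {
        df <- as.data.frame(stats::setNames(
          rep(list(logical(0)), length(cols)), cols))
        return(df)
      }
      as.data.frame(x, stringsAsFactors = FALSE)
    }
    structure(list(
      participant_id = obj$participant_id, trial_id = obj$trial_id,
      recipe = obj$recipe, mode = obj$mode,
      events = as_df(obj$events, c("t", "subaction", "duration",
                                   "quantity", "execution_flag")),
      cues = as_df(obj$cues, c("t", "reason", "recommended")),
      errors = as_df(obj$errors, c("step_index", "t", "code",
                                   "recoverable", "subaction", "note")),
      outcome = obj$outcome,
      termination_message = obj$termination_message %||% NA_character_,
      completion_time_raw = obj$completion_time_raw,
      boil_time = obj$boil_time), class = "trial_record")
  })
}

#' Load and validate a data file against a named schema
#'
#' @param path File path.
#' @param schema One of `"task_model"`, `"trial_log"`, `"scores"`,
#'   `"baseline"`, `"control_sequences"`.
#' @return The validated object (task model, list of trial records, or
#'   data.frame).
#' @export
validate_and_load <- function(path, schema = c("task_model", "trial_log",
                                               "scores", "baseline",
                                               "control_sequences")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(schema,
    task_model = read_task_model(path),
    trial_log = read_trial_log(path),
    scores = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE)
      need <- c("participant", "group", "assessment", "recoverable",
                "nonrecoverable", "mean_time")
      miss <- setdiff(need, names(df))
      if (length(miss) > 0) {
        stop("scores file ", path, " lacks column(s): ",
             paste(miss, collapse = ", "))
      }
      df
    },
    baseline = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE)
      miss <- setdiff(c("group", "age", "sex"), names(df))
      if (length(miss) > 0) {
        stop("baseline file ", path, " lacks column(s): ",
             paste(miss, collapse = ", "))
      }
      df
    },
    control_sequences = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE)
      need <- c("sequence_id", "step_index", "subaction_id")
      miss <- setdiff(need, names(df))
      if (length(miss) > 0) {
        stop("control-sequence file ", path, " lacks column(s): ",
             paste(miss, collapse = ", "))
      }
      df
    })
}

#' Top-level command-line interface
#'
#' Subcommands: `estimate-model`, `run-trial`, `simulate-cohort`,
#' `analyze`, `make-fixtures`; every subcommand takes `--seed`.  Intended
#' to be driven by the thin wrapper script in `inst/cli/teatask`:
#' \preformatted{Rscript inst/cli/teatask run-trial --recipe WTS \
#'     --mode training --behaviour script.csv --seed 7}
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status (0 on success, 2 on usage error),
#'   invisibly.
#' @export
teatask_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: teatask <command> [options]",
    "commands:",
    "  estimate-model  --sequences seqs.csv --out model.json [--pseudocount 0.5]",
    "  run-trial       --recipe BT|BTS|WT|WTS --mode training|assessment",
    "                  --behaviour script.csv --out trial.jsonl [--model model.json] [--seed N]",
    "  simulate-cohort --out-prefix PREFIX [--n-per-group 15] [--effect 0.5] [--seed N]",
    "  analyze         --scores scores.csv [--impute M] [--seed N] --out report.json",
    "  make-fixtures   --out-dir DIR [--seed N]",
    "  --version", sep = "\n")
  if (length(argv) == 0) { message(usage); return(invisible(2L)) }
  if (argv[1] == "--version") {
    cat("teatask schema versions: task-model 1.0, trial-log 1.0\n")
    return(invisible(0L))
  }
  cmd <- argv[1]
  opts <- parse_cli_opts(argv[-1])
  seed <- as.integer(opts[["seed"]] %||% 1)
  status <- tryCatch({
    switch(cmd,
      "estimate-model" = {
        seqs <- validate_and_load(req_opt(opts, "sequences"),
                                  "control_sequences")
        pc <- as.numeric(opts[["pseudocount"]] %||% 0.5)
        model <- tea_task_model(split(seqs$subaction_id, seqs$sequence_id),
                                pseudocount = pc)
        write_task_model(model, req_opt(opts, "out"))
        message("model written to ", opts[["out"]])
        0L
      },
      "run-trial" = {
        model <- if (!is.null(opts[["model"]]))
          validate_and_load(opts[["model"]], "task_model") else
          tea_task_model()
        rec <- model$recipes[[req_opt(opts, "recipe")]]
        if (is.null(rec)) stop("unknown recipe: ", opts[["recipe"]])
        steps <- utils::read.csv(req_opt(opts, "behaviour"),
                                 stringsAsFactors = FALSE)
        beh <- scripted_behaviour(steps)
        mode <- opts[["mode"]] %||% "assessment"
        set.seed(seed)
        tr <- if (mode == "training")
          run_training_trial(beh, model, rec) else
          run_assessment_trial(beh, model, rec)
        write_trial_log(tr, req_opt(opts, "out"))
        message("outcome: ", tr$outcome, "; errors: ", nrow(tr$errors),
                "; cues: ", nrow(tr$cues))
        0L
      },
      "simulate-cohort" = {
        cfg <- cohort_config(
          n_per_group = as.integer(opts[["n-per-group"]] %||% 15),
          training_effect = as.numeric(opts[["effect"]] %||% 0.5),
          seed = seed)
        cohort <- simulate_cohort(cfg, tea_task_model())
        prefix <- req_opt(opts, "out-prefix")
        utils::write.csv(cohort$baseline,
                         paste0(prefix, "_baseline.csv"), row.names = FALSE)
        utils::write.csv(cohort$scores,
                         paste0(prefix, "_scores.csv"), row.names = FALSE)
        message("cohort written to ", prefix, "_{baseline,scores}.csv")
        0L
      },
      "analyze" = {
        scores <- validate_and_load(req_opt(opts, "scores"), "scores")
        m <- as.integer(opts[["impute"]] %||% 0)
        res <- analyze_cohort(scores, m = m, seed = seed)
        report <- list(
          n_analysed = res$n_analysed,
          anova_errors = res$anova_errors$effects,
          anova_time = res$anova_time$effects,
          posthoc_errors = res$anova_errors$posthoc,
          contrast_means = colMeans(res$contrasts[, -(1:2)]))
        jsonlite::write_json(report, req_opt(opts, "out"),
                             auto_unbox = TRUE, digits = NA, na = "null",
                             pretty = TRUE)
        print(res$anova_errors)
        print(res$anova_time)
        0L
      },
      "make-fixtures" = {
        dir <- req_opt(opts, "out-dir")
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(baseline_characteristics(),
                         file.path(dir, "baseline_characteristics.csv"),
                         row.names = FALSE)
        cfg <- cohort_config(n_per_group = 3, seed = seed)
        demo <- simulate_cohort(cfg, tea_task_model())
        utils::write.csv(demo$scores, file.path(dir, "demo_scores.csv"),
                         row.names = FALSE)
        write_task_model(tea_task_model(),
                         file.path(dir, "tea_model.json"))
        message("fixtures written to ", dir)
        0L
      },
      { message("unknown command: ", cmd, "\n", usage); 2L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE; i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  opts
}

req_opt <- function(opts, key) {
  if (is.null(opts[[key]])) stop("missing required option --", key)
  opts[[key]]
}
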