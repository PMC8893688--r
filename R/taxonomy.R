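#' The ten-category neuropsychological error taxonomy
#'
#' Action errors in tea making are described in neuropsychological terms
#' (addition, perseveration, omission, ...) rather than task-specific terms,
#' so that findings can be compared across activities of daily living.
#' Four categories are non-recoverable (they irreversibly spoil the drink)
#' and six are recoverable (a later action or cue can still correct them).
#'
#' The row order of the returned table is also the fixed priority order used
#' by [classify_event()] when an event matches more than one category:
#' non-recoverable categories take precedence (they drive trial
#' termination), and within each class categories are tried in listing
#' order.
#'
#' The `trained_by_system` flag marks categories detected and cued online by
#' the training subsystem; the remainder are assessment-only annotations
#' (execution quality and the quantity thresholds require observation that a
#' discrete action log does not carry).  Membership of this flag is a
#' documented convention, not a property of the taxonomy itself.
#'
#' @return A data.frame with columns `code`, `label`, `recoverable`,
#'   `trained_by_system` and `definition`, one row per category.
#' @examples
#' error_categories()[, c("code", "recoverable")]
#' @export
error_categories <- function() {
  ERROR_CATS
}

# built once at load time; classification sits on the simulator's hot path
ERROR_CATS <- local({
  data.frame(
    code = c("N-ADD", "N-OSUB", "N-KET", "N-QMO",
             "R-CP", "R-EX", "R-RP", "R-SEQ", "R-QMU", "R-SOM"),
    label = c("addition", "object substitution", "kettle operation error",
              "quantity overestimation",
              "continuous perseveration", "execution",
              "recurrent perseveration", "sequence",
              "quantity underestimation", "step omission"),
    recoverable = c(FALSE, FALSE, FALSE, FALSE,
                    TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    trained_by_system = c(TRUE, TRUE, TRUE, FALSE,
                          FALSE, FALSE, TRUE, TRUE, FALSE, TRUE),
    definition = c(
      "Adding an extra component action that is not required in the action sequence (e.g. sugar or milk when not required).",
      "An intended action carried out with an incorrect object (e.g. coffee instead of tea).",
      "Kettle not operated correctly (no water added, not switched on, boil not awaited).",
      "Adding too much of an ingredient (e.g. overfilling the cup).",
      "Inappropriate prolongation of a behaviour without interruption (e.g. stirring for more than 10 s).",
      "Clumsy execution of an otherwise correct action (annotated, not inferred from the log).",
      "Repeating a step after its goal has been achieved, later in the sequence.",
      "Performing an action in the wrong order (e.g. removing the teabag before adding water).",
      "Adding too little of an ingredient (e.g. cup under 50% full).",
      "Omitting a required step (e.g. failing to add sugar, milk or teabag)."),
    stringsAsFactors = FALSE
  )
})

RECOVERABLE_BY_CODE <- stats::setNames(ERROR_CATS$recoverable, ERROR_CATS$code)

#' Is an error category recoverable?
#'
#' @param code Character vector of category codes (e.g. `"R-SOM"`).
#' @return Logical vector; `TRUE` for recoverable categories.
#' @examples
#' is_recoverable(c("N-ADD", "R-SOM"))
#' @export
is_recoverable <- function(code) {
  out <- RECOVERABLE_BY_CODE[code]
  if (anyNA(out)) {
    stop("unknown error category code: ",
         paste(unique(code[is.na(out)]), collapse = ", "))
  }
  unname(out)
}
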