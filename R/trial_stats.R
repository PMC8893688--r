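#' Score one assessment (8 tea-making trials)
#'
#' The accuracy measure is the summed number of classified errors across
#' the 8 trials, split into recoverable and non-recoverable; the speed
#' measure is the mean completion time with the (variable) kettle boil
#' time deducted from each trial.
#'
#' @param trials List of `"trial_record"`s from one participant's
#'   assessment; normally 8 (fewer is accepted and flagged
#'   `incomplete` for downstream imputation).
#' @return A list with `participant_id`, `n_trials`, `recoverable_errors`,
#'   `nonrecoverable_errors`, `mean_time` and `incomplete`.
#' @export
score_assessment <- function(trials) {
  ids <- unique(vapply(trials, function(tr)
    as.character(tr$participant_id), character(1)))
  if (length(ids) > 1L) {
    stop("trials from more than one participant: ",
         paste(ids, collapse = ", "))
  }
  tallies <- lapply(trials, tally_errors)
  rec <- sum(vapply(tallies, `[[`, numeric(1), "recoverable"))
  nonrec <- sum(vapply(tallies, `[[`, numeric(1), "nonrecoverable"))
  times <- vapply(trials, function(tr)
    tr$completion_time_raw - tr$boil_time, numeric(1))
  list(participant_id = ids, n_trials = length(trials),
       recoverable_errors = rec, nonrecoverable_errors = nonrec,
       mean_time = mean(times), incomplete = length(trials) < 8L)
}

#' Build crossover contrasts for one participant
#'
#' Change scores between assessments, signed earlier minus later so that a
#' positive value is a reduction (improvement).  The experimental contrast
#' brackets tea-making training, the control contrast brackets stepping
#' training, and the follow-up contrast runs from post-tea-training to
#' follow-up; with Group 1 training tea in Phase 1 and Group 2 in Phase 2
#' this maps to assessments 1-2, 2-3, 2-4 for Group 1 and 2-3, 1-2, 3-4
#' for Group 2.
#'
#' @param scores A data.frame with columns `assessment` (1..4) and one or
#'   more measure columns (e.g. `recoverable`, `nonrecoverable`,
#'   `mean_time`) for a single participant.
#' @param group 1 or 2.
#' @return A data.frame with one row per measure and columns `measure`,
#'   `experimental`, `control`, `followup`.
#' @export
build_contrasts <- function(scores, group) {
  if (!group %in% c(1, 2)) stop("unknown group: ", group)
  if (!all(1:4 %in% scores$assessment)) {
    stop("need all 4 assessments (impute first)")
  }
  measures <- setdiff(names(scores),
                      c("participant", "group", "assessment"))
  a <- scores[match(1:4, scores$assessment), measures, drop = FALSE]
  pick <- function(i, j) as.numeric(a[i, ]) - as.numeric(a[j, ])
  if (group == 1) {
    out <- data.frame(measure = measures, experimental = pick(1, 2),
                      control = pick(2, 3), followup = pick(2, 4))
  } else {
    out <- data.frame(measure = measures, experimental = pick(2, 3),
                      control = pick(1, 2), followup = pick(3, 4))
  }
  out
}

#' Build the contrast table for a whole cohort
#'
#' @param scores Long scores table (`participant`, `group`, `assessment`,
#'   `recoverable`, `nonrecoverable`, `mean_time`).  Participants with any
#'   missing assessment are dropped (complete-case) — impute first to keep
#'   them.
#' @return A wide data.frame, one row per participant, with columns
#'   `rec_exp`, `rec_ctl`, `rec_fup`, `non_exp`, `non_ctl`, `non_fup`,
#'   `time_exp`, `time_ctl`, `time_fup`.
#' @export
build_contrasts_cohort <- function(scores) {
  out <- lapply(split(scores, scores$participant), function(df) {
    if (anyNA(df[, c("recoverable", "nonrecoverable", "mean_time")]) ||
        !all(1:4 %in% df$assessment)) {
      return(NULL)
    }
    cc <- build_contrasts(df[, c("assessment", "recoverable",
                                 "nonrecoverable", "mean_time")],
                          df$group[1])
    data.frame(participant = df$participant[1], group = df$group[1],
               rec_exp = cc$experimental[1], rec_ctl = cc$control[1],
               rec_fup = cc$followup[1],
               non_exp = cc$experimental[2], non_ctl = cc$control[2],
               non_fup = cc$followup[2],
               time_exp = cc$experimental[3], time_ctl = cc$control[3],
               time_fup = cc$followup[3])
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

# Shared repeated-measures engine: Y is an n x k response matrix, idata
# describes the within-subject design.  Returns per-effect F tests with
# Mauchly's test and the Greenhouse-Geisser correction via car::Anova.
rm_anova_engine <- function(Y, idata, idesign) {
  if (nrow(Y) < 3L) stop("need at least 3 participants for RM-ANOVA")
  mod <- stats::lm(Y ~ 1)
  av <- car::Anova(mod, idata = idata, idesign = idesign, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests
  effects <- setdiff(rownames(ut), "(Intercept)")
  sph <- s$sphericity.tests
  adj <- s$pval.adjustments
  res <- data.frame(
    effect = effects,
    df1 = ut[effects, "num Df"], df2 = ut[effects, "den Df"],
    F = ut[effects, "F value"], p = ut[effects, "Pr(>F)"],
    mauchly_W = NA_real_, mauchly_p = NA_real_,
    gg_eps = NA_real_, p_gg = NA_real_,
    stringsAsFactors = FALSE)
  if (!is.null(sph) && nrow(sph) > 0) {
    idx <- match(rownames(sph), res$effect)
    keep <- !is.na(idx)
    res$mauchly_W[idx[keep]] <- sph[keep, "Test statistic"]
    res$mauchly_p[idx[keep]] <- sph[keep, "p-value"]
  }
  if (!is.null(adj) && nrow(adj) > 0) {
    idx <- match(rownames(adj), res$effect)
    keep <- !is.na(idx) & !is.na(adj[, "GG eps"])
    res$gg_eps[idx[keep]] <- adj[keep, "GG eps"]
    res$p_gg[idx[keep]] <- adj[keep, "Pr(>F[GG])"]
  }
  # report the GG-corrected p whenever Mauchly's test is significant;
  # effects with < 3 levels have no sphericity assumption (eps = 1)
  res$gg_applied <- !is.na(res$mauchly_p) & res$mauchly_p < 0.05
  res$p_reported <- ifelse(res$gg_applied, res$p_gg, res$p)
  res$df1_reported <- ifelse(res$gg_applied, res$df1 * res$gg_eps, res$df1)
  res$df2_reported <- ifelse(res$gg_applied, res$df2 * res$gg_eps, res$df2)
  rownames(res) <- NULL
  res
}

# All pairwise paired comparisons between the columns of a matrix:
# mean difference +/- SE and an uncorrected paired t-test.
pairwise_paired <- function(M, correction = "none") {
  cols <- colnames(M)
  pairs <- utils::combn(seq_along(cols), 2)
  out <- apply(pairs, 2, function(ij) {
    d <- M[, ij[1]] - M[, ij[2]]
    n <- sum(!is.na(d)); se <- stats::sd(d, na.rm = TRUE) / sqrt(n)
    tval <- mean(d, na.rm = TRUE) / se
    data.frame(level1 = cols[ij[1]], level2 = cols[ij[2]],
               mean_diff = mean(d, na.rm = TRUE), se = se, t = tval,
               df = n - 1, p = 2 * stats::pt(-abs(tval), n - 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (correction == "bonferroni") {
    out$p <- pmin(1, out$p * nrow(out))
  }
  out
}

#' 2 x 3 repeated-measures ANOVA on error change scores
#'
#' The main accuracy analysis: within-subject factors error type
#' (recoverable, non-recoverable) and contrast (experimental, control,
#' follow-up) on the change scores.  Mauchly's sphericity test is applied
#' to every effect with 3 or more levels and the Greenhouse-Geisser
#' corrected p-value is reported whenever it is significant.  Post-hoc
#' pairwise comparisons (uncorrected paired t-tests by default, matching
#' the reported analysis; Bonferroni optionally) cover the two marginal
#' factors and the error-type difference within each contrast.
#'
#' @param contrasts Wide contrast table from [build_contrasts_cohort()]
#'   (columns `rec_exp`, `rec_ctl`, `rec_fup`, `non_exp`, `non_ctl`,
#'   `non_fup`).
#' @param correction Post-hoc p-value correction: `"none"` (default) or
#'   `"bonferroni"`.
#' @return An object of class `"anova_table"`: list with `effects` (one
#'   row per effect: F, dfs, p, Mauchly W and p, GG epsilon, corrected and
#'   reported p) and `posthoc` (named list of pairwise tables).
#' @export
rm_anova_2x3 <- function(contrasts, correction = "none") {
  need <- c("rec_exp", "rec_ctl", "rec_fup", "non_exp", "non_ctl", "non_fup")
  if (!all(need %in% names(contrasts))) {
    stop("contrast table must have columns ", paste(need, collapse = ", "))
  }
  Y <- as.matrix(contrasts[, need])
  idata <- data.frame(
    errtype = factor(rep(c("recoverable", "nonrecoverable"), each = 3),
                     levels = c("recoverable", "nonrecoverable")),
    contrast = factor(rep(c("experimental", "control", "followup"), 2),
                      levels = c("experimental", "control", "followup")))
  eff <- rm_anova_engine(Y, idata, ~ errtype * contrast)
  # marginals for post-hoc comparisons
  type_means <- cbind(recoverable = rowMeans(Y[, 1:3]),
                      nonrecoverable = rowMeans(Y[, 4:6]))
  con_means <- cbind(experimental = rowMeans(Y[, c(1, 4)]),
                     control = rowMeans(Y[, c(2, 5)]),
                     followup = rowMeans(Y[, c(3, 6)]))
  within <- lapply(1:3, function(j) {
    M <- Y[, c(j, j + 3), drop = FALSE]
    colnames(M) <- c("recoverable", "nonrecoverable")
    pairwise_paired(M, correction)
  })
  names(within) <- c("experimental", "control", "followup")
  structure(list(
    effects = eff,
    posthoc = list(error_type = pairwise_paired(type_means, correction),
                   contrast = pairwise_paired(con_means, correction),
                   type_within_contrast = do.call(rbind, lapply(
                     names(within), function(nm)
                       cbind(contrast = nm, within[[nm]])))),
    n = nrow(Y)
  ), class = "anova_table")
}

#' One-way repeated-measures ANOVA on completion-time change scores
#'
#' @param time_contrasts A data.frame or matrix with columns for the
#'   experimental, control and follow-up time change scores (`time_exp`,
#'   `time_ctl`, `time_fup`, or any three columns in that order).
#' @inheritParams rm_anova_2x3
#' @return An `"anova_table"` (see [rm_anova_2x3()]).
#' @export
rm_anova_oneway <- function(time_contrasts, correction = "none") {
  M <- as.matrix(time_contrasts)
  if (ncol(M) != 3L) stop("expected 3 contrast columns")
  colnames(M) <- c("experimental", "control", "followup")
  idata <- data.frame(contrast = factor(
    c("experimental", "control", "followup"),
    levels = c("experimental", "control", "followup")))
  eff <- rm_anova_engine(M, idata, ~ contrast)
  structure(list(effects = eff,
                 posthoc = list(contrast = pairwise_paired(M, correction)),
                 n = nrow(M)),
            class = "anova_table")
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Repeated-measures ANOVA (n =", x$n, ")\n")
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("  %-22s F(%.3f, %.3f) = %.3f, p = %.4g%s\n",
                eff$effect[i], eff$df1_reported[i], eff$df2_reported[i],
                eff$F[i], eff$p_reported[i],
                if (isTRUE(eff$gg_applied[i]))
                  sprintf("  [Greenhouse-Geisser, eps = %.3f]",
                          eff$gg_eps[i]) else ""))
  }
  invisible(x)
}

#' Convert long scores to the wide (one row per participant) layout
#'
#' @param scores Long scores table from [simulate_cohort()].
#' @return Wide data.frame with columns `rec_1..rec_4`, `non_1..non_4`,
#'   `time_1..time_4`.
#' @export
scores_wide <- function(scores) {
  out <- lapply(split(scores, scores$participant), function(df) {
    df <- df[match(1:4, df$assessment), ]
    data.frame(participant = df$participant[!is.na(df$participant)][1],
               group = df$group[!is.na(df$group)][1],
               rec_1 = df$recoverable[1], rec_2 = df$recoverable[2],
               rec_3 = df$recoverable[3], rec_4 = df$recoverable[4],
               non_1 = df$nonrecoverable[1], non_2 = df$nonrecoverable[2],
               non_3 = df$nonrecoverable[3], non_4 = df$nonrecoverable[4],
               time_1 = df$mean_time[1], time_2 = df$mean_time[2],
               time_3 = df$mean_time[3], time_4 = df$mean_time[4])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$participant), ]
}

#' Impute missing assessment scores by chained equations
#'
#' Iterated stochastic regression: each incomplete score column is
#' regressed, in turn, on all other score columns and the supplied
#' baseline auxiliaries over the originally observed rows, and its missing
#' cells are replaced by the regression prediction plus normal noise at
#' the residual scale.  Cycling continues for `maxit` sweeps; `m`
#' independent chains give `m` completed datasets.  With no missing data
#' the input is returned unchanged (in `m` copies).
#'
#' @param scores Wide scores table from [scores_wide()]; missingness is
#'   only expected in the score columns.
#' @param aux Optional data.frame of complete numeric baseline auxiliaries
#'   (same row order as `scores`), e.g. age and years post stroke.
#' @param m Number of imputed datasets.
#' @param maxit Chained-equation sweeps per dataset.
#' @param seed Integer seed.
#' @return A list of `m` completed data.frames.
#' @export
impute_missing <- function(scores, aux = NULL, m = 5, maxit = 10,
                           seed = 1L) {
  id_cols <- intersect(c("participant", "group"), names(scores))
  sc <- scores[, setdiff(names(scores), id_cols), drop = FALSE]
  if (!all(vapply(sc, is.numeric, logical(1)))) {
    stop("score columns must be numeric")
  }
  all_missing <- names(sc)[vapply(sc, function(x) all(is.na(x)), logical(1))]
  if (length(all_missing) > 0L) {
    stop("variable(s) with all values missing: ",
         paste(all_missing, collapse = ", "))
  }
  if (!is.null(aux)) {
    aux <- as.data.frame(aux)
    if (anyNA(aux)) stop("auxiliary variables must be complete")
  }
  incomplete <- names(sc)[vapply(sc, anyNA, logical(1))]
  if (length(incomplete) == 0L) {
    return(replicate(m, scores, simplify = FALSE))
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  obs_mask <- !is.na(sc)
  lapply(seq_len(m), function(chain) {
    dat <- sc
    for (j in incomplete) {
      dat[[j]][is.na(dat[[j]])] <- mean(dat[[j]], na.rm = TRUE)
    }
    X_aux <- if (is.null(aux)) NULL else aux
    for (it in seq_len(maxit)) {
      for (j in incomplete) {
        mis <- !obs_mask[, j]
        preds <- dat[, setdiff(names(dat), j), drop = FALSE]
        if (!is.null(X_aux)) preds <- cbind(preds, X_aux)
        dfit <- cbind(y = dat[[j]], preds)
        fit <- stats::lm(y ~ ., data = dfit[!mis, , drop = FALSE])
        sigma <- summary(fit)$sigma
        if (!is.finite(sigma)) sigma <- 0
        # small samples can leave the design rank-deficient; the dropped
        # aliased terms simply contribute nothing to the prediction
        mu <- suppressWarnings(
          stats::predict(fit, newdata = preds[mis, , drop = FALSE]))
        dat[[j]][mis] <- mu + stats::rnorm(sum(mis), 0, sigma)
      }
    }
    cbind(scores[, id_cols, drop = FALSE], dat)
  })
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' @param estimates Numeric matrix, one row per imputation, one column per
#'   quantity.
#' @param variances Matrix of squared standard errors, same shape.
#' @return data.frame with pooled `estimate`, `se`, `df` (Rubin's
#'   small-sample degrees of freedom) per quantity.
#' @export
pool_rubin <- function(estimates, variances) {
  estimates <- as.matrix(estimates); variances <- as.matrix(variances)
  m <- nrow(estimates)
  qbar <- colMeans(estimates)
  ubar <- colMeans(variances)
  b <- apply(estimates, 2, stats::var)
  total <- ubar + (1 + 1 / m) * b
  r <- (1 + 1 / m) * b / ubar
  df <- (m - 1) * (1 + 1 / r)^2
  data.frame(quantity = colnames(estimates) %||% seq_along(qbar),
             estimate = qbar, se = sqrt(total), df = df,
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inter-rater reliability of trial scoring
#'
#' Pearson correlations between two assessors' per-trial total time and
#' total error counts on a common subset of trials.
#'
#' @param rater_a,rater_b data.frames with columns `total_time` and
#'   `total_errors`, one row per jointly scored trial, in matching order.
#' @return data.frame with one row per measure: `measure`, `r`, `n`, `p`.
#' @export
interrater_reliability <- function(rater_a, rater_b) {
  if (nrow(rater_a) != nrow(rater_b)) stop("rater tables differ in length")
  if (nrow(rater_a) < 3L) stop("need at least 3 paired trials")
  one <- function(measure) {
    x <- rater_a[[measure]]; y <- rater_b[[measure]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("zero variance in '", measure,
           "': correlation undefined for constant scores")
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(measure = measure, r = unname(ct$estimate),
               n = length(x), p = ct$p.value, stringsAsFactors = FALSE)
  }
  rbind(one("total_time"), one("total_errors"))
}

#' Univariable logistic models of improvement
#'
#' One logistic regression per baseline characteristic (univariable,
#' deliberately: the small samples this design targets do not support
#' multivariable fits), reporting the odds ratio of improvement with a
#' 95% Wald interval.  Complete separation is flagged rather than
#' silently estimated.
#'
#' @param improved Logical (or 0/1) outcome vector; the convention for
#'   "improved" is a positive experimental contrast in total errors.
#' @param predictors data.frame of baseline characteristics, one column
#'   per candidate predictor.
#' @return data.frame with `predictor`, `or`, `ci_lower`, `ci_upper`, `p`,
#'   `separation`.
#' @export
improvement_model <- function(improved, predictors) {
  improved <- as.numeric(improved)
  if (length(unique(improved[!is.na(improved)])) < 2) {
    stop("outcome has no variation")
  }
  out <- lapply(names(predictors), function(nm) {
    x <- predictors[[nm]]
    if (length(unique(x[!is.na(x)])) < 2) {
      stop("constant predictor: ", nm)
    }
    fit <- suppressWarnings(stats::glm(improved ~ x,
                                       family = stats::binomial()))
    co <- summary(fit)$coefficients
    beta <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
    mu <- stats::fitted(fit)
    sep <- !fit$converged || any(mu < 1e-8 | mu > 1 - 1e-8) ||
      abs(beta) > 15
    data.frame(predictor = nm, or = exp(beta),
               ci_lower = exp(beta - 1.96 * se),
               ci_upper = exp(beta + 1.96 * se),
               p = co["x", "Pr(>|z|)"], separation = sep,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify participants as improved or not
#'
#' The working definition of "improved" is a positive experimental
#' contrast in total (recoverable + non-recoverable) errors, i.e. fewer
#' errors after tea-making training than before.  No other threshold is
#' imposed; the choice is a documented convention.
#'
#' @param contrasts Wide contrast table from [build_contrasts_cohort()].
#' @return Logical vector, one flag per participant.
#' @export
improved_flags <- function(contrasts) {
  (contrasts$rec_exp + contrasts$non_exp) > 0
}

#' Per-category error breakdown before and after training
#'
#' Counts each error category across a set of pre-training trials and a
#' set of post-training trials, with relative proportions computed within
#' the recoverable and non-recoverable classes (each class's proportions
#' sum to 1 per period when the class is non-empty).
#'
#' @param pre_trials,post_trials Lists of classified `"trial_record"`s.
#' @return data.frame with `code`, `recoverable`, `pre`, `post`,
#'   `pre_prop`, `post_prop`; categories never observed are dropped (an
#'   error-free input yields zero rows).
#' @export
error_breakdown <- function(pre_trials, post_trials) {
  cats <- error_categories()
  count_all <- function(trials) {
    counts <- stats::setNames(integer(nrow(cats)), cats$code)
    for (tr in trials) {
      counts <- counts + tally_errors(tr)$by_category
    }
    counts
  }
  pre <- count_all(pre_trials); post <- count_all(post_trials)
  prop_within <- function(counts) {
    out <- rep(NA_real_, length(counts))
    for (cls in c(TRUE, FALSE)) {
      i <- cats$recoverable == cls
      tot <- sum(counts[i])
      if (tot > 0) out[i] <- counts[i] / tot
    }
    out
  }
  res <- data.frame(code = cats$code, recoverable = cats$recoverable,
                    pre = as.integer(pre), post = as.integer(post),
                    pre_prop = prop_within(pre),
                    post_prop = prop_within(post),
                    stringsAsFactors = FALSE)
  res[res$pre + res$post > 0, , drop = FALSE]
}

#' Descriptive summary of a baseline table
#'
#' @param table A baseline-characteristics table (e.g.
#'   [baseline_characteristics()] or [generate_baseline_table()]); needs
#'   `age`, `sex` and, if present, `years_post_stroke` (a band such as
#'   `">5"` is read as its bound).
#' @return List with `n`, `age_mean`, `age_sd`, `pct_female`,
#'   `years_mean`, `years_sd`.  Standard deviations are `NA` for a
#'   single-row table.
#' @export
summarize_baseline <- function(table) {
  if (nrow(table) == 0L) stop("empty baseline table")
  years <- if ("years_post_stroke" %in% names(table)) {
    as.numeric(sub("^>", "", as.character(table$years_post_stroke)))
  } else NULL
  list(n = nrow(table),
       age_mean = mean(table$age),
       age_sd = if (nrow(table) > 1) stats::sd(table$age) else NA_real_,
       pct_female = 100 * mean(table$sex == "F"),
       years_mean = if (is.null(years)) NA_real_ else mean(years),
       years_sd = if (is.null(years) || nrow(table) < 2) NA_real_
                  else stats::sd(years))
}

#' Participant-flow (CONSORT) accounting
#'
#' Applies the stated exclusions to the consented sample: participants who
#' withdrew after randomisation but before the baseline assessment
#' contribute no data; post-trial exclusions are removed from analysis;
#' in-trial dropouts remain in the analysed set via imputation but leave
#' the complete-case set.
#'
#' @param consented Participants who gave informed consent.
#' @param withdrew_pre_assessment Withdrawals before any assessment.
#' @param excluded_post_trial Exclusions after trial completion (e.g.
#'   diagnosis revision, protocol deviation).
#' @param dropped_during_trial In-trial dropouts whose missing assessments
#'   are imputed.
#' @return List with `consented`, `analysed`, `complete_cases`.
#' @export
consort_flow <- function(consented = 29, withdrew_pre_assessment = 2,
                         excluded_post_trial = 2,
                         dropped_during_trial = 3) {
  analysed <- consented - withdrew_pre_assessment - excluded_post_trial
  list(consented = consented, analysed = analysed,
       complete_cases = analysed - dropped_during_trial)
}

#' Sample-size planning with dropout inflation
#'
#' Solves the standard power equation for the requested test family and
#' inflates the result by `1/(1 - dropout_fraction)`.  The family must be
#' given explicitly — an effect size alone does not determine the test.
#'
#' @param effect_size Standardised effect size (Cohen's d for the t
#'   families).
#' @param alpha Type-I error rate.
#' @param power Target power; must exceed `alpha`.
#' @param dropout_fraction Anticipated dropout (0 for none).
#' @param family `"paired_t"`, `"one_sample_t"` or `"two_sample_t"`.
#' @return List with `n_required` (per group, after inflation), `n_raw`
#'   (before inflation) and the inputs.
#' @export
plan_sample_size <- function(effect_size, alpha = 0.05, power,
                             dropout_fraction = 0,
                             family = c("paired_t", "one_sample_t",
                                        "two_sample_t")) {
  family <- match.arg(family)
  if (power <= alpha) stop("power must exceed alpha")
  if (dropout_fraction < 0 || dropout_fraction >= 1) {
    stop("dropout_fraction must be in [0, 1)")
  }
  type <- switch(family, paired_t = "paired", one_sample_t = "one.sample",
                 two_sample_t = "two.sample")
  n_raw <- stats::power.t.test(delta = effect_size, sd = 1,
                               sig.level = alpha, power = power,
                               type = type)$n
  list(n_required = ceiling(ceiling(n_raw) / (1 - dropout_fraction)),
       n_raw = n_raw, effect_size = effect_size, alpha = alpha,
       power = power, dropout_fraction = dropout_fraction,
       family = family)
}

#' Run the full crossover analysis on a cohort's scores
#'
#' Convenience wrapper: optionally imputes missing assessments, builds the
#' contrast table, and runs the 2 x 3 error ANOVA and the one-way time
#' ANOVA.  With `m > 0` and missing data, analyses are run on each
#' completed dataset and the contrast means are pooled by Rubin's rules;
#' the ANOVA of the first completed dataset is returned as the headline
#' table alongside the per-imputation p-values.
#'
#' @param scores Long scores table.
#' @param aux Optional auxiliaries for imputation (see [impute_missing()]).
#' @param m Number of imputations (0 = complete cases only).
#' @param seed Seed for the imputation draws.
#' @return List with `contrasts`, `anova_errors`, `anova_time`,
#'   `pooled_means` (NULL without imputation) and `n_analysed`.
#' @export
analyze_cohort <- function(scores, aux = NULL, m = 0, seed = 1L) {
  wide <- scores_wide(scores)
  has_missing <- anyNA(wide[, -(1:2)])
  pooled <- NULL; per_imp_p <- NULL
  if (has_missing && m > 0) {
    completed <- impute_missing(wide, aux = aux, m = m, seed = seed)
    long_list <- lapply(completed, wide_to_long)
    con_list <- lapply(long_list, build_contrasts_cohort)
    cols <- c("rec_exp", "rec_ctl", "rec_fup", "non_exp", "non_ctl",
              "non_fup", "time_exp", "time_ctl", "time_fup")
    est <- t(vapply(con_list, function(cc) colMeans(cc[, cols]),
                    numeric(length(cols))))
    vars <- t(vapply(con_list, function(cc)
      apply(cc[, cols], 2, function(x) stats::var(x) / length(x)),
      numeric(length(cols))))
    pooled <- pool_rubin(est, vars)
    anv <- lapply(con_list, function(cc) rm_anova_2x3(cc))
    per_imp_p <- t(vapply(anv, function(a) a$effects$p_reported,
                          numeric(nrow(anv[[1]]$effects))))
    colnames(per_imp_p) <- anv[[1]]$effects$effect
    contrasts <- con_list[[1]]
  } else {
    contrasts <- build_contrasts_cohort(scores)
  }
  list(contrasts = contrasts,
       anova_errors = rm_anova_2x3(contrasts),
       anova_time = rm_anova_oneway(contrasts[, c("time_exp", "time_ctl",
                                                  "time_fup")]),
       pooled_means = pooled, per_imputation_p = per_imp_p,
       n_analysed = nrow(contrasts))
}

# inverse of scores_wide
wide_to_long <- function(wide) {
  out <- lapply(seq_len(nrow(wide)), function(i) {
    data.frame(participant = wide$participant[i], group = wide$group[i],
               assessment = 1:4,
               recoverable = as.numeric(wide[i, paste0("rec_", 1:4)]),
               nonrecoverable = as.numeric(wide[i, paste0("non_", 1:4)]),
               mean_time = as.numeric(wide[i, paste0("time_", 1:4)]))
  })
  do.call(rbind, out)
}
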