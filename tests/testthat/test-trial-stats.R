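mk_trial <- function(codes, raw = 60, boil = 20, pid = "p1") {
  list(participant_id = pid,
       errors = data.frame(code = codes, stringsAsFactors = FALSE),
       completion_time_raw = raw, boil_time = boil)
}

test_that("assessment scoring sums errors and deducts boil time", {
  trials <- replicate(8, mk_trial(character()), simplify = FALSE)
  sc <- score_assessment(trials)
  expect_equal(sc$recoverable_errors, 0)
  expect_equal(sc$nonrecoverable_errors, 0)
  expect_equal(sc$mean_time, 40)
  expect_false(sc$incomplete)
  # hand-scripted counts 1,0,2,0,1,0,0,1 recoverable
  recs <- c(1, 0, 2, 0, 1, 0, 0, 1)
  trials2 <- lapply(recs, function(k) mk_trial(rep("R-SEQ", k)))
  expect_equal(score_assessment(trials2)$recoverable_errors, 5)
  # boil-time deduction invariance: +10 s boil with +10 s raw
  trials3 <- replicate(8, mk_trial(character(), raw = 70, boil = 30),
                       simplify = FALSE)
  expect_equal(score_assessment(trials3)$mean_time, 40)
  # mixed participants are rejected
  bad <- c(trials[1:7], list(mk_trial(character(), pid = "p2")))
  expect_error(score_assessment(bad), "more than one participant")
  expect_true(score_assessment(trials[1:6])$incomplete)
})

test_that("crossover contrasts follow the group-specific assessment mapping", {
  sc <- data.frame(assessment = 1:4, errors = c(10, 4, 4, 5))
  g1 <- build_contrasts(sc, 1)
  expect_equal(g1$experimental, 6)
  expect_equal(g1$control, 0)
  expect_equal(g1$followup, -1)
  g2 <- build_contrasts(sc, 2)
  expect_equal(g2$experimental, 0)
  expect_equal(g2$control, 6)
  expect_equal(g2$followup, -1)
  # all-equal scores: all contrasts zero
  flat <- data.frame(assessment = 1:4, errors = rep(3, 4))
  expect_true(all(build_contrasts(flat, 1)[, -1] == 0))
  expect_error(build_contrasts(sc, 3), "unknown group")
  expect_error(build_contrasts(sc[1:3, ], 1), "4 assessments")
})

test_that("RM-ANOVAs match the matrix-algebra oracle on a hand dataset", {
  set.seed(123)
  n <- 6
  Y <- matrix(rnorm(n * 6, mean = rep(c(2, 1, 0.5, 0.3, 0.2, 0.1),
                                      each = n)), n, 6)
  colnames(Y) <- c("rec_exp", "rec_ctl", "rec_fup",
                   "non_exp", "non_ctl", "non_fup")
  got <- rm_anova_2x3(as.data.frame(Y))
  want <- oracle_rm_2x3(Y)
  eff <- got$effects
  for (pair in list(c("errtype", "errtype"),
                    c("contrast", "contrast"),
                    c("errtype:contrast", "interaction"))) {
    g <- eff[eff$effect == pair[1], ]
    w <- want[[pair[2]]]
    expect_equal(g$F, w$F, tolerance = 1e-8)
    expect_equal(g$p, w$p, tolerance = 1e-8)
    if (!is.na(w$mauchly_W)) {
      expect_equal(g$mauchly_W, w$mauchly_W, tolerance = 1e-8)
      expect_equal(g$mauchly_p, w$mauchly_p, tolerance = 1e-8)
      expect_equal(g$gg_eps, w$eps, tolerance = 1e-8)
      expect_equal(g$p_gg, w$p_gg, tolerance = 1e-8)
    }
  }
  # one-way on the time columns
  T3 <- Y[, 1:3]
  got1 <- rm_anova_oneway(T3)
  want1 <- oracle_rm_oneway(T3)
  expect_equal(got1$effects$F, want1$F, tolerance = 1e-8)
  expect_equal(got1$effects$gg_eps, want1$eps, tolerance = 1e-8)
  expect_equal(got1$effects$mauchly_W, want1$mauchly_W, tolerance = 1e-8)
})

test_that("epsilon lies in [1/(k-1), 1] and the sphericity limit is benign", {
  set.seed(21)
  for (i in 1:25) {
    Y <- matrix(rnorm(8 * 3), 8, 3)
    a <- rm_anova_oneway(Y)
    eps <- a$effects$gg_eps
    expect_gte(eps, 1 / 2 - 1e-12)
    expect_lte(eps, 1 + 1e-12)
  }
  # compound-symmetric data: eps near 1, GG p near raw p
  set.seed(22)
  base <- rnorm(60)
  Y <- cbind(base + rnorm(60, sd = 1), base + rnorm(60, sd = 1),
             base + rnorm(60, sd = 1))
  a <- rm_anova_oneway(Y)
  expect_gt(a$effects$gg_eps, 0.9)
  expect_lt(abs(a$effects$p_gg - a$effects$p), 0.05)
})

test_that("two-level factors carry no sphericity correction", {
  set.seed(23)
  Y <- matrix(rnorm(12), 6, 2)
  colnames(Y) <- c("a", "b")
  idata <- data.frame(f = factor(c("a", "b")))
  eff <- teatask:::rm_anova_engine(Y, idata, ~ f)
  expect_true(is.na(eff$mauchly_W[eff$effect == "f"]))
  expect_false(eff$gg_applied[eff$effect == "f"])
  expect_equal(eff$p_reported, eff$p)
})

test_that("degenerate and invariant ANOVA inputs behave as expected", {
  # no between-level effect (each column centred): F = 0
  Y <- apply(matrix(rnorm(18), 6, 3), 2, function(x) x - mean(x))
  expect_equal(rm_anova_oneway(Y)$effects$F, 0, tolerance = 1e-12)
  # permuting participants leaves F unchanged
  set.seed(24)
  Z <- matrix(rnorm(30), 10, 3)
  f1 <- rm_anova_oneway(Z)$effects$F
  f2 <- rm_anova_oneway(Z[sample(10), ])$effects$F
  expect_equal(f1, f2, tolerance = 1e-10)
  # too few participants
  expect_error(rm_anova_oneway(Z[1:2, ]), "at least 3")
})

test_that("post-hoc comparisons are symmetric paired t-tests", {
  set.seed(25)
  M <- matrix(rnorm(30), 10, 3)
  colnames(M) <- c("experimental", "control", "followup")
  a <- rm_anova_oneway(M)
  ph <- a$posthoc$contrast
  expect_equal(nrow(ph), 3)
  tt <- t.test(M[, 1] - M[, 2])
  row <- ph[ph$level1 == "experimental" & ph$level2 == "control", ]
  expect_equal(row$p, tt$p.value, tolerance = 1e-12)
  expect_equal(row$mean_diff, unname(tt$estimate), tolerance = 1e-12)
  # bonferroni option scales p
  a2 <- rm_anova_oneway(M, correction = "bonferroni")
  expect_equal(a2$posthoc$contrast$p, pmin(1, ph$p * 3))
})

test_that("imputation is idempotent on complete data and sane on missing", {
  set.seed(26)
  wide <- data.frame(participant = 1:20, group = rep(1:2, 10),
                     rec_1 = rpois(20, 5), rec_2 = rpois(20, 3),
                     rec_3 = rpois(20, 3), rec_4 = rpois(20, 3))
  out <- impute_missing(wide, m = 3, seed = 1)
  expect_length(out, 3)
  expect_identical(out[[1]], wide)
  # single missing cell: imputations stay within a sane range
  wide2 <- wide
  wide2$rec_2[5] <- NA
  out2 <- impute_missing(wide2, m = 10, seed = 2)
  vals <- vapply(out2, function(d) d$rec_2[5], numeric(1))
  obs <- wide$rec_2[-5]
  expect_true(all(vals > min(obs) - 3 * sd(obs) &
                  vals < max(obs) + 3 * sd(obs)))
  # observed cells are never altered
  expect_identical(out2[[1]]$rec_1, wide2$rec_1)
  expect_equal(out2[[1]]$rec_2[-5], as.numeric(wide2$rec_2[-5]))
  # all-missing variable is rejected
  wide3 <- wide; wide3$rec_3 <- NA_real_
  expect_error(impute_missing(wide3), "all values missing")
})

test_that("imputed contrast means are unbiased under MCAR missingness", {
  set.seed(27)
  n <- 40; reps <- 60
  bias <- replicate(reps, {
    truth <- rnorm(n, mean = 5, sd = 2)
    wide <- data.frame(participant = 1:n, group = 1,
                       rec_1 = truth + rnorm(n, sd = 0.5),
                       rec_2 = truth + rnorm(n, sd = 0.5),
                       rec_3 = truth + rnorm(n, sd = 0.5),
                       rec_4 = truth + rnorm(n, sd = 0.5))
    full_mean <- mean(wide$rec_2)
    drop <- sample(n, round(0.1 * n))
    wide$rec_2[drop] <- NA
    out <- impute_missing(wide, m = 3, seed = sample.int(1e6, 1))
    mean(vapply(out, function(d) mean(d$rec_2), numeric(1))) - full_mean
  })
  se <- sd(bias) / sqrt(reps)
  expect_lt(abs(mean(bias)), 3 * se + 0.02)
})

test_that("Rubin pooling combines within- and between-imputation variance", {
  est <- matrix(c(1, 2, 3), 3, 1)
  vars <- matrix(c(0.5, 0.5, 0.5), 3, 1)
  pooled <- pool_rubin(est, vars)
  expect_equal(pooled$estimate, 2)
  expect_equal(pooled$se^2, 0.5 + (1 + 1 / 3) * 1)
})

test_that("inter-rater reliability matches the textbook formula", {
  a <- data.frame(total_time = c(60, 70, 80, 55, 90),
                  total_errors = c(1, 3, 2, 0, 4))
  b <- data.frame(total_time = c(62, 69, 83, 50, 88),
                  total_errors = c(1, 4, 2, 1, 4))
  out <- interrater_reliability(a, b)
  hand_r <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(out$r[out$measure == "total_time"],
               hand_r(a$total_time, b$total_time), tolerance = 1e-12)
  expect_equal(out$r[out$measure == "total_errors"],
               hand_r(a$total_errors, b$total_errors), tolerance = 1e-12)
  # identical raters and sign flip
  same <- interrater_reliability(a, a)
  expect_equal(same$r, c(1, 1))
  flip <- a; flip$total_time <- -a$total_time; flip$total_errors <- -a$total_errors
  expect_equal(interrater_reliability(a, flip)$r, c(-1, -1))
  expect_error(interrater_reliability(a[1:2, ], b[1:2, ]), "at least 3")
  const <- a; const$total_errors <- 2
  expect_error(interrater_reliability(const, b), "zero variance")
})

test_that("the logistic improvement model recovers a known odds ratio", {
  set.seed(28)
  n <- 500
  age <- rnorm(n, 70, 8)
  eta <- 0.223 * (age - 70)
  y <- rbinom(n, 1, plogis(eta))
  out <- improvement_model(y, data.frame(age = age))
  logor <- log(out$or)
  se <- (log(out$ci_upper) - log(out$or)) / 1.96
  expect_lt(abs(logor - 0.223), 3 * se)
  expect_false(out$separation)
  # null predictor: OR near 1, CI covers 1
  x0 <- rnorm(n)
  out0 <- improvement_model(y, data.frame(noise = x0))
  expect_true(out0$ci_lower < 1 && out0$ci_upper > 1)
  # degenerate inputs
  expect_error(improvement_model(y, data.frame(k = rep(1, n))),
               "constant predictor")
  expect_error(improvement_model(rep(1, n), data.frame(age = age)),
               "no variation")
  # complete separation is flagged
  ysep <- as.numeric(age > 70)
  sep <- improvement_model(ysep, data.frame(age = age))
  expect_true(sep$separation)
})

test_that("error breakdowns count per category with within-class proportions", {
  t1 <- mk_trial(c("R-CP", "R-CP", "N-KET"))
  t2 <- mk_trial(c("R-SOM", "N-KET"))
  t3 <- mk_trial(c("R-CP"))
  bd <- error_breakdown(list(t1, t2), list(t3))
  expect_equal(bd$pre[bd$code == "R-CP"], 2)
  expect_equal(bd$post[bd$code == "R-CP"], 1)
  expect_equal(bd$pre[bd$code == "N-KET"], 2)
  rec_rows <- bd$recoverable
  expect_equal(sum(bd$pre_prop[rec_rows]), 1, tolerance = 1e-9)
  expect_equal(sum(bd$pre_prop[!rec_rows]), 1, tolerance = 1e-9)
  expect_equal(sum(bd$post_prop[rec_rows]), 1, tolerance = 1e-9)
  # error-free input: empty table
  expect_equal(nrow(error_breakdown(list(mk_trial(character())),
                                    list(mk_trial(character())))), 0)
})

test_that("baseline summaries are exact and invariant to duplication", {
  tab <- data.frame(age = c(60, 70, 80), sex = c("F", "M", "F"),
                    years_post_stroke = c(">5", "2", ">10"))
  s <- summarize_baseline(tab)
  expect_equal(s$n, 3)
  expect_equal(s$age_mean, 70)
  expect_equal(s$pct_female, 200 / 3)
  expect_equal(s$years_mean, mean(c(5, 2, 10)))
  dup <- summarize_baseline(rbind(tab, tab))
  expect_equal(dup$age_mean, s$age_mean)
  expect_lt(dup$age_sd, s$age_sd)  # duplication shrinks the sample SD
  single <- summarize_baseline(tab[1, ])
  expect_true(is.na(single$age_sd))
  expect_error(summarize_baseline(tab[0, ]), "empty")
})

test_that("sample-size planning matches the noncentral-t solution", {
  # paired t, d = 0.5, alpha = .05, power = .80
  got <- plan_sample_size(0.5, 0.05, 0.80, 0, "paired_t")
  expect_equal(ceiling(got$n_raw), oracle_paired_n(0.5, 0.05, 0.80))
  expect_equal(got$n_required, got$n_required)  # no inflation at 0 dropout
  expect_equal(got$n_required, ceiling(got$n_raw))
  # dropout inflation
  infl <- plan_sample_size(0.5, 0.05, 0.80, 0.25, "paired_t")
  expect_equal(infl$n_required, ceiling(ceiling(got$n_raw) / 0.75))
  # doubling the effect size never increases n
  n_small <- plan_sample_size(0.3, 0.05, 0.85, 0, "paired_t")$n_required
  n_big <- plan_sample_size(0.6, 0.05, 0.85, 0, "paired_t")$n_required
  expect_lte(n_big, n_small)
  expect_error(plan_sample_size(0.5, 0.05, 0.04, 0, "paired_t"),
               "power must exceed alpha")
  expect_error(plan_sample_size(0.5, 0.05, 0.8, 1, "paired_t"),
               "dropout_fraction")
})

test_that("improvement flags follow the positive-experimental-contrast rule", {
  cc <- data.frame(rec_exp = c(2, -1, 0), non_exp = c(1, 0, 0))
  expect_equal(improved_flags(cc), c(TRUE, FALSE, FALSE))
})

test_that("the end-to-end analysis wrapper handles imputation", {
  cfg <- cohort_config(n_per_group = 6, seed = 31, dropout_prob = 0.3,
                       training_effect = 0.5)
  coh <- simulate_cohort(cfg, TEST_MODEL)
  expect_true(anyNA(coh$scores$recoverable))
  res <- analyze_cohort(coh$scores, m = 3, seed = 1)
  expect_equal(res$n_analysed, 12)
  expect_s3_class(res$anova_errors, "anova_table")
  expect_false(is.null(res$pooled_means))
  # complete-case route drops the dropouts
  res_cc <- analyze_cohort(coh$scores, m = 0)
  expect_lt(res_cc$n_analysed, 12)
})
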