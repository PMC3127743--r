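test_that("trapezoidal AUC equals the all-pairs concordance oracle", {
  set.seed(61)
  for (rep in 1:25) {
    n <- sample(5:200, 1)
    # discrete scores guarantee plenty of ties
    score <- sample(0:10, n, replace = TRUE)
    outcome <- stats::runif(n) < 0.4
    if (!any(outcome) || all(outcome)) next
    roc <- roc_auc(score, outcome)
    expect_equal(roc$auc, auc_pairwise_oracle(score, outcome),
                 tolerance = 1e-12)
  }
})

test_that("ROC curve is a valid monotone path from (0,0) to (1,1)", {
  set.seed(62)
  score <- stats::rnorm(300)
  outcome <- stats::runif(300) < stats::plogis(score)
  roc <- roc_auc(score, outcome)
  pts <- roc$points
  expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("AUC anchors: perfect separation, chance level, rank invariance", {
  expect_equal(roc_auc(c(2, 3, 0, 1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1.0)
  set.seed(63)
  score <- stats::rnorm(10000)
  outcome <- stats::runif(10000) < 0.5  # independent of score
  expect_equal(roc_auc(score, outcome)$auc, 0.5, tolerance = 0.04)
  # adding a constant never changes the curve
  roc1 <- roc_auc(score, outcome)
  roc2 <- roc_auc(score + 17.3, outcome)
  expect_equal(roc1$points, roc2$points)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "one positive and one negative")
})

test_that("in-package AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(64)
  for (rep in 1:5) {
    score <- c(stats::rnorm(80), stats::rnorm(60, mean = 0.8))
    outcome <- rep(c(FALSE, TRUE), c(80, 60))
    ref <- as.numeric(pROC::auc(pROC::roc(outcome, score, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(score, outcome)$auc, ref, tolerance = 1e-10)
  }
})

test_that("logistic fit reports reference rows as exactly 1.00 without CI", {
  coh <- generate_cohort(2500, seed = 71)
  m <- fit_logistic(coh)
  refs <- m$terms[m$terms$is_reference, ]
  expect_setequal(paste(refs$covariate, refs$level),
                  c("sex man", "age_group 75_79", "reason new_problem",
                    "level very_high"))
  expect_true(all(refs$estimate == 1.00))
  expect_true(all(is.na(refs$ci_low)))
  # non-reference terms have ci_low <= estimate <= ci_high
  est <- m$terms[!m$terms$is_reference, ]
  expect_true(all(est$ci_low <= est$estimate & est$estimate <= est$ci_high))
  expect_gte(m$c_statistic, 0.5)  # on its own training cohort
  expect_true(all(m$pseudo_r2 > 0 & m$pseudo_r2 < 1))
  expect_equal(m$n_positive + m$n_negative, 2500)
})

test_that("null covariate effects are recovered as OR about 1", {
  prof <- nordic_profile()
  prof$outcome_model$or[] <- 1
  coh <- generate_cohort(15000, seed = 72, profile = prof)
  m <- fit_logistic(coh)
  est <- m$terms[!m$terms$is_reference, ]
  expect_true(all(abs(log(est$estimate)) < 0.25))
  expect_gt(mean(est$ci_low < 1 & est$ci_high > 1), 0.8)
})

test_that("logistic refits recover generating odds ratios", {
  coh <- generate_cohort(8000, seed = 73)
  m <- fit_logistic(coh)
  gen <- nordic_profile()$outcome_model$or
  lv <- m$terms[m$terms$covariate == "level" & !m$terms$is_reference, ]
  for (i in seq_len(nrow(lv))) {
    want <- unname(gen[paste0("level_", lv$level[i])])
    expect_equal(lv$estimate[i], want, tolerance = 0.30,
                 info = lv$level[i])
  }
})

test_that("single-class endpoints and missing levels raise clear errors", {
  coh <- generate_cohort(50, seed = 74)
  df <- as.data.frame(coh)
  df$discharge_outcome <- "home"
  expect_error(fit_logistic(maple_cohort(df)), "single outcome class")
})

test_that("the adverse endpoint excludes 'other' outcomes by default", {
  coh <- generate_cohort(4000, seed = 75)
  ep <- mapleAC:::episode_table(coh)
  m_home <- fit_logistic(coh, endpoint_spec("discharged_home"))
  m_adv <- fit_logistic(coh, endpoint_spec("adverse_at_discharge"))
  n_other <- sum(ep$discharge_outcome == "other")
  expect_gt(n_other, 0)
  expect_equal(m_home$n_positive + m_home$n_negative, nrow(ep))
  expect_equal(m_adv$n_positive + m_adv$n_negative, nrow(ep) - n_other)
  # 'other' disposition is configurable
  m_adv2 <- fit_logistic(coh, endpoint_spec("adverse_at_discharge",
                                            other = "negative"))
  expect_equal(m_adv2$n_positive + m_adv2$n_negative, nrow(ep))
})

test_that("Cox fits recover generating hazard ratios and respect ties choice", {
  coh <- generate_cohort(8000, seed = 76)
  m <- fit_cox(coh)
  gen <- nordic_profile()$survival_model$hr
  lv <- m$terms[m$terms$covariate == "level" & !m$terms$is_reference, ]
  for (i in seq_len(nrow(lv))) {
    want <- unname(gen[paste0("level_", lv$level[i])])
    expect_equal(lv$estimate[i], want, tolerance = 0.25, info = lv$level[i])
  }
  dx <- m$terms[grepl("^dxgrp", m$terms$covariate), ]
  expect_equal(dx$estimate[dx$covariate == "dxgrp_neoplasms"],
               unname(gen["dxgrp_neoplasms"]), tolerance = 0.25)
  m_b <- fit_cox(coh, ties = "breslow")
  expect_false(identical(m$terms$estimate, m_b$terms$estimate))
  expect_equal(m$terms$estimate, m_b$terms$estimate, tolerance = 0.05)
})

test_that("hazard ratios are invariant to a common time-scale change", {
  prof <- nordic_profile()
  prof$survival_model$censor_day <- 182L
  coh <- generate_cohort(4000, seed = 77, profile = prof)
  m1 <- fit_cox(coh)
  df <- as.data.frame(coh)
  df$days_to_event <- df$days_to_event * 2L  # doubled scale, <= 364
  m2 <- fit_cox(maple_cohort(df))
  expect_equal(m1$terms$estimate, m2$terms$estimate, tolerance = 1e-8)
})

test_that("a cohort with no events cannot be fit", {
  coh <- generate_cohort(60, seed = 78)
  df <- as.data.frame(coh)
  df$event_died <- FALSE
  df <- df[df$discharge_outcome != "dead" | TRUE, ]
  df$discharge_outcome[df$discharge_outcome == "dead"] <- "institution"
  expect_error(fit_cox(maple_cohort(df)), "no death events")
})

test_that("chi-squared cross-tabulation matches hand anchors", {
  a <- generate_cohort(300, seed = 81)
  res_same <- crosstab_compare(a, a, "sex")
  expect_equal(res_same$statistic, 0)
  expect_equal(res_same$p_value, 1)

  # 2x2 table (10,0 ; 0,10): Pearson statistic 20
  b <- generate_cohort(40, seed = 82)
  df <- as.data.frame(b)
  ids <- unique(df$patient_id)
  df$sex <- ifelse(df$patient_id %in% ids[1:10], "woman", "man")
  ca <- maple_cohort(df[df$patient_id %in% ids[1:10], ])
  cb <- maple_cohort(df[df$patient_id %in% ids[11:20], ])
  res <- crosstab_compare(ca, cb, "sex")
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1)
  # symmetric in cohort order
  expect_equal(crosstab_compare(cb, ca, "sex")$statistic, res$statistic)
})

test_that("report tables round-trip through CSV", {
  coh <- generate_cohort(1500, seed = 83)
  results <- list(fit_logistic(coh), fit_cox(coh))
  tmp <- withr::local_tempfile(fileext = ".csv")
  rep1 <- report_tables(results, tmp, seed = 83)
  back <- read_model_report(tmp)
  expect_equal(back$estimate, rep1$estimate, tolerance = 1e-12)
  expect_equal(back$c_statistic, rep1$c_statistic, tolerance = 1e-12)
  expect_identical(back$tree_version, rep1$tree_version)
  expect_true(all(back$seed == 83))

  empty <- report_tables(list())
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("estimate", "ci_low", "c_statistic") %in% names(empty)))
})

test_that("confidence intervals cover the generating effects at near-nominal rates", {
  # coverage of the generating level-effect ORs/HRs over replicate cohorts
  n_rep <- 30
  cover_or <- cover_hr <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    coh <- generate_cohort(5000, seed = 9000 + r)
    m <- fit_logistic(coh)
    t_low <- m$terms[m$terms$covariate == "level" & m$terms$level == "low", ]
    cover_or[r] <- t_low$ci_low <= 12.20 && 12.20 <= t_low$ci_high
    mc <- fit_cox(coh)
    t_vh <- mc$terms[mc$terms$covariate == "level" &
                       mc$terms$level == "very_high", ]
    cover_hr[r] <- t_vh$ci_low <= 3.70 && 3.70 <= t_vh$ci_high
  }
  expect_gte(mean(cover_or), 0.85)
  expect_gte(mean(cover_hr), 0.85)
})
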