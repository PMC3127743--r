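## Synthetic episode-cohort generator. Covariates (sex, age group, living
## arrangement, reason for hospitalisation) and per-timepoint priority
## levels are drawn independently from published cohort marginals; item
## patterns are then inverse-constructed so that the shipped tree maps each
## assessment to exactly the drawn level (closed-loop guarantee, verified
## on every generated cohort); binary discharge outcomes are drawn from a
## logistic model whose odds ratios are the published coefficient sets with
## the intercept solved so the marginal endpoint rate matches the published
## proportion; days to death are exponential with covariate-dependent rate
## (proportional hazards exact) censored at 365 days.

## ---- published coefficient sets (generating values) -----------------------

or_set <- function(sex, age, reason, levels, reference_level, endpoint,
                   timepoint, target_rate) {
  or <- c(sex_woman = sex,
          age_80_84 = age[1], age_85_89 = age[2], age_90_plus = age[3],
          reason_exacerbation = reason[1], reason_both = reason[2],
          level_low = levels[1], level_mild = levels[2],
          level_moderate = levels[3], level_high = levels[4],
          level_very_high = levels[5])
  list(endpoint = endpoint, timepoint = timepoint,
       reference_level = reference_level, or = or,
       target_rate = target_rate)
}

nordic_outcome_models <- function() {
  home <- 626 / 763; adverse <- 123 / 763
  list(
    home_premorbid = or_set(1.12, c(0.82, 0.86, 0.61), c(1.46, 0.76),
                            c(12.20, 4.23, 2.38, 2.08, 1.00), "very_high",
                            "discharge_home", "premorbid", home),
    home_admission = or_set(1.20, c(0.74, 0.85, 0.54), c(1.21, 0.68),
                            c(11.63, 8.77, 3.67, 1.69, 1.00), "very_high",
                            "discharge_home", "admission", home),
    home_day7 = or_set(1.12, c(0.79, 0.88, 0.62), c(1.27, 0.77),
                       c(19.11, 9.46, 2.83, 2.24, 1.00), "very_high",
                       "discharge_home", "day7_discharge", home),
    adverse_premorbid = or_set(1.15, c(1.21, 1.22, 1.66), c(0.83, 1.39),
                               c(1.00, 3.50, 8.58, 9.39, 19.31), "low",
                               "adverse_discharge", "premorbid", adverse),
    adverse_admission = or_set(1.06, c(1.39, 1.23, 1.93), c(1.04, 1.60),
                               c(1.00, 1.97, 5.69, 12.56, 22.54), "low",
                               "adverse_discharge", "admission", adverse),
    adverse_day7 = or_set(1.13, c(1.27, 1.17, 1.65), c(0.99, 1.41),
                          c(1.00, 4.22, 18.06, 25.09, 51.71), "low",
                          "adverse_discharge", "day7_discharge", adverse))
}

canadian_outcome_models <- function() {
  home <- 197 / 393; adverse <- 155 / 393
  list(
    home_premorbid = or_set(1.31, c(0.94, 0.50, 0.29), c(2.26, 0.71),
                            c(11.60, 10.89, 5.39, 3.10, 1.00), "very_high",
                            "discharge_home", "premorbid", home),
    home_admission = or_set(1.18, c(0.88, 0.51, 0.35), c(1.92, 0.59),
                            c(9.39, 25.80, 4.70, 1.65, 1.00), "very_high",
                            "discharge_home", "admission", home),
    home_day7 = or_set(0.94, c(0.81, 0.39, 0.45), c(2.77, 0.74),
                       c(49.98, 36.40, 5.83, 4.77, 1.00), "very_high",
                       "discharge_home", "day7_discharge", home),
    adverse_premorbid = or_set(0.72, c(0.92, 1.61, 2.56), c(0.64, 1.32),
                               c(1.00, 1.42, 2.71, 5.15, 10.79), "low",
                               "adverse_discharge", "premorbid", adverse),
    adverse_admission = or_set(0.81, c(1.58, 2.34, 0.79), c(0.79, 1.77),
                               c(1.00, 0.42, 1.43, 6.73, 8.01), "low",
                               "adverse_discharge", "admission", adverse))
}

hr_set <- function(sex, age, reason, levels, dx, timepoint) {
  list(timepoint = timepoint,
       hr = c(sex_woman = sex,
              age_80_84 = age[1], age_85_89 = age[2], age_90_plus = age[3],
              reason_exacerbation = reason[1], reason_both = reason[2],
              level_low = levels[1], level_mild = levels[2],
              level_moderate = levels[3], level_high = levels[4],
              level_very_high = levels[5],
              dxgrp_neoplasms = dx[1], dxgrp_mental_behavioral = dx[2],
              dxgrp_respiratory = dx[3]),
       reference_level = "low",
       target_death_rate = 202 / 763, censor_day = 365L)
}

nordic_survival_models <- function() {
  list(
    premorbid = hr_set(0.61, c(1.17, 1.25, 1.52), c(1.46, 1.94),
                       c(1.00, 1.61, 1.76, 2.82, 3.70),
                       c(3.21, 0.43, 1.59), "premorbid"),
    admission = hr_set(0.58, c(1.23, 1.25, 1.56), c(1.52, 1.98),
                       c(1.00, 0.85, 1.31, 2.26, 2.71),
                       c(3.29, 0.48, 1.62), "admission"),
    day7 = hr_set(0.60, c(1.18, 1.23, 1.50), c(1.51, 1.94),
                  c(1.00, 1.78, 1.77, 2.69, 3.63),
                  c(3.44, 0.46, 1.61), "day7_discharge"))
}

## ---- cohort profiles ------------------------------------------------------

#' Calibrated cohort profiles
#'
#' `nordic_profile()` and `canadian_profile()` return the full parameter
#' set of the synthetic generator calibrated to the corresponding study
#' cohort: covariate marginals, per-timepoint priority-level marginals,
#' outcome coefficient sets (odds ratios with intercepts solved to match
#' the marginal endpoint rate), and — for the Nordic cohort, which has a
#' one-year follow-up — a proportional-hazards survival model for days to
#' death. The `outcome` argument selects which coefficient set generates
#' the binary discharge outcome; `survival` selects the hazard-ratio set.
#'
#' @param outcome name of the generating outcome model (see
#'   `names(nordic_outcome_models())`): endpoint x assessment time point.
#' @param survival for `nordic_profile()`: which survival coefficient set
#'   drives days to death (`"premorbid"`, `"admission"`, `"day7"`).
#' @return a list of generator parameters (class `maple_profile`).
#' @export
nordic_profile <- function(outcome = "home_premorbid",
                           survival = "premorbid") {
  om <- nordic_outcome_models()
  if (!outcome %in% names(om))
    stop("unknown outcome model '", outcome, "'")
  sm <- nordic_survival_models()
  if (!survival %in% names(sm))
    stop("unknown survival model '", survival, "'")
  structure(list(
    name = "nordic",
    demo = list(
      p_woman = 497 / 763,
      p_age = c(`75_79` = 203, `80_84` = 232, `85_89` = 210,
                `90_plus` = 118) / 763,
      p_lived_alone = 468 / 763,
      p_prior_hosp = 239 / 763,
      p_reason = c(new_problem = 304, exacerbation = 298, both = 160) / 762),
    levels = list(
      premorbid = c(low = 301, mild = 79, moderate = 184, high = 151,
                    very_high = 48) / 763,
      admission = c(low = 91, mild = 65, moderate = 341, high = 193,
                    very_high = 73) / 763,
      day7_discharge = c(low = 176, mild = 101, moderate = 237, high = 181,
                         very_high = 68) / 763),
    day7_missing_rate = 0,
    outcome_model = om[[outcome]],
    other_rate = 14 / 763,
    survival_model = sm[[survival]],
    dx_prevalence = c(dxgrp_neoplasms = 0.15, dxgrp_mental_behavioral = 0.10,
                      dxgrp_respiratory = 0.20),
    one_year = c(home = 426, institution = 79, other = 56) / 561
  ), class = "maple_profile")
}

#' @rdname nordic_profile
#' @export
canadian_profile <- function(outcome = "home_premorbid") {
  om <- canadian_outcome_models()
  if (!outcome %in% names(om))
    stop("unknown outcome model '", outcome, "'")
  structure(list(
    name = "canadian",
    demo = list(
      p_woman = 234 / 393,
      p_age = c(`75_79` = 84, `80_84` = 119, `85_89` = 116,
                `90_plus` = 74) / 393,
      p_lived_alone = 117 / 393,
      p_prior_hosp = 123 / 393,
      p_reason = c(new_problem = 211, exacerbation = 126, both = 56) / 393),
    levels = list(
      premorbid = c(low = 124, mild = 45, moderate = 88, high = 92,
                    very_high = 44) / 393,
      admission = c(low = 57, mild = 37, moderate = 119, high = 118,
                    very_high = 62) / 393,
      day7_discharge = c(low = 59, mild = 37, moderate = 105, high = 108,
                         very_high = 69) / 378),
    day7_missing_rate = 15 / 393,
    outcome_model = om[[outcome]],
    other_rate = 41 / 393,
    survival_model = NULL,
    dx_prevalence = c(dxgrp_neoplasms = 0.15, dxgrp_mental_behavioral = 0.10,
                      dxgrp_respiratory = 0.20),
    one_year = NULL
  ), class = "maple_profile")
}

validate_profile <- function(p) {
  stopifnot(inherits(p, "maple_profile"))
  for (tp in names(p$levels))
    if (abs(sum(p$levels[[tp]]) - 1) > 1e-9)
      stop("level marginals for ", tp, " do not sum to 1")
  if (abs(sum(p$demo$p_age) - 1) > 1e-9) stop("age marginals do not sum to 1")
  if (abs(sum(p$demo$p_reason) - 1) > 1e-9)
    stop("reason marginals do not sum to 1")
  invisible(p)
}

## ---- intercept / baseline-rate solving ------------------------------------

## linear predictor (log OR / log HR scale) for covariate columns
linear_predictor <- function(coefs, sex, age_group, reason, level,
                             dx = NULL) {
  lp <- log(coefs["sex_woman"]) * (sex == "woman") +
    log(coefs["age_80_84"]) * (age_group == "80_84") +
    log(coefs["age_85_89"]) * (age_group == "85_89") +
    log(coefs["age_90_plus"]) * (age_group == "90_plus") +
    log(coefs["reason_exacerbation"]) * (reason == "exacerbation") +
    log(coefs["reason_both"]) * (reason == "both") +
    log(coefs[paste0("level_", as.character(level))])
  if (!is.null(dx))
    for (cc in colnames(dx))
      lp <- lp + log(coefs[cc]) * dx[, cc]
  unname(lp)
}

## covariate joint distribution under independence, as a grid with weights
covariate_grid <- function(profile, timepoint, with_dx = FALSE) {
  demo <- profile$demo
  g <- expand.grid(sex = c("woman", "man"),
                   age_group = names(demo$p_age),
                   reason = names(demo$p_reason),
                   level = maple_levels(),
                   stringsAsFactors = FALSE)
  w <- ifelse(g$sex == "woman", demo$p_woman, 1 - demo$p_woman) *
    demo$p_age[g$age_group] * demo$p_reason[g$reason] *
    profile$levels[[timepoint]][g$level]
  if (with_dx) {
    dxp <- profile$dx_prevalence
    for (cc in names(dxp)) {
      g2 <- rbind(g, g); g2[[cc]] <- rep(c(0, 1), each = nrow(g))
      w <- c(w * (1 - dxp[cc]), w * dxp[cc])
      g <- g2
    }
  }
  g$weight <- unname(w)
  g
}

## intercept such that the marginal endpoint rate matches the target
solve_logistic_intercept <- function(profile, model) {
  g <- covariate_grid(profile, model$timepoint)
  lp <- linear_predictor(model$or, g$sex, g$age_group, g$reason, g$level)
  stats::uniroot(function(b0) sum(g$weight * stats::plogis(b0 + lp)) -
                   model$target_rate,
                 interval = c(-25, 25), tol = 1e-10)$root
}

## baseline daily hazard such that cumulative death probability by the
## censoring day matches the target one-year death rate
solve_baseline_hazard <- function(profile, model) {
  g <- covariate_grid(profile, model$timepoint, with_dx = TRUE)
  dx <- as.matrix(g[, names(profile$dx_prevalence), drop = FALSE])
  lp <- linear_predictor(model$hr, g$sex, g$age_group, g$reason, g$level,
                         dx = dx)
  f <- function(log_lambda0) {
    sum(g$weight * (1 - exp(-exp(log_lambda0 + lp) * model$censor_day))) -
      model$target_death_rate
  }
  exp(stats::uniroot(f, interval = c(-20, 0), tol = 1e-12)$root)
}

## ---- inverse item construction --------------------------------------------

## Construct, for each requested level, a 31-item assessment pattern that
## the reference tree maps back to exactly that level. Patterns are
## randomised within provably level-preserving bounds.
construct_items <- function(levels, n = length(levels)) {
  items <- as.data.frame(matrix(0L, nrow = n, ncol = length(item_codes())),
                         stringsAsFactors = FALSE)
  names(items) <- item_codes()
  items$goes_out <- 1L
  lv <- as.character(levels)

  i_low <- which(lv == "low")
  if (length(i_low)) {
    for (cc in c("adl_hygiene", "adl_toilet_use", "adl_locomotion",
                 "adl_eating"))
      items[[cc]][i_low] <- sample(0:1, length(i_low), replace = TRUE)
  }

  i_mild <- which(lv == "mild")
  if (length(i_mild)) {
    items$meal_preparation_problem[i_mild] <- 1L
    items$shopping_problem[i_mild] <-
      sample(0:1, length(i_mild), replace = TRUE)
  }

  i_mod <- which(lv == "moderate")
  if (length(i_mod)) {
    k <- length(i_mod)
    for (cc in c("fall_recent", "swallowing_difficulty",
                 "medication_management_problem", "decision_making_decline"))
      items[[cc]][i_mod] <- stats::rbinom(k, 1L, 0.4)
    none <- i_mod[items$fall_recent[i_mod] +
                    items$swallowing_difficulty[i_mod] +
                    items$medication_management_problem[i_mod] +
                    items$decision_making_decline[i_mod] == 0L]
    items$fall_recent[none] <- 1L
    # mild ADL / cognitive impairment (hierarchy <= 2, CPS <= 2)
    for (cc in c("adl_hygiene", "adl_toilet_use", "adl_locomotion",
                 "adl_eating"))
      items[[cc]][i_mod] <- sample(0:3, k, replace = TRUE)
    items$short_term_memory_problem[i_mod] <- stats::rbinom(k, 1L, 0.3)
  }

  i_high <- which(lv == "high")
  if (length(i_high)) {
    k <- length(i_high)
    path <- sample(c("adl", "cps", "behavior", "ulcer"), k, replace = TRUE)
    p_adl <- i_high[path == "adl"]
    if (length(p_adl)) {
      # hierarchy 3..5 without activating the risk screener
      sub <- sample(3:5, length(p_adl), replace = TRUE)
      items$adl_hygiene[p_adl][sub == 3] <- 4L
      items$adl_locomotion[p_adl][sub == 4] <- 4L
      items$adl_eating[p_adl][sub == 5] <- 6L
    }
    p_cps <- i_high[path == "cps"]
    if (length(p_cps)) {
      # CPS 3 (moderate) or 5 (severe, eating independent)
      sev <- sample(c(FALSE, TRUE), length(p_cps), replace = TRUE)
      items$short_term_memory_problem[p_cps][!sev] <- 1L
      items$decision_making[p_cps][!sev] <- 2L
      items$decision_making[p_cps][sev] <- 3L
    }
    p_beh <- i_high[path == "behavior"]
    if (length(p_beh)) {
      beh <- c("verbally_abusive", "physically_abusive",
               "socially_inappropriate", "resists_care")
      pick <- sample(beh, length(p_beh), replace = TRUE)
      for (cc in beh) items[[cc]][p_beh][pick == cc] <- 1L
    }
    items$pressure_ulcer[i_high[path == "ulcer"]] <- 1L
  }

  i_vh <- which(lv == "very_high")
  if (length(i_vh)) {
    k <- length(i_vh)
    # severity component: severe ADL, severe cognition, or behaviour
    path <- sample(c("adl", "cps", "behavior"), k, replace = TRUE)
    p_adl <- i_vh[path == "adl"]
    items$adl_eating[p_adl] <- sample(4:6, length(p_adl), replace = TRUE)
    items$adl_locomotion[p_adl] <- sample(4:6, length(p_adl), replace = TRUE)
    p_cps <- i_vh[path == "cps"]
    items$decision_making[p_cps] <- 3L
    items$making_self_understood[p_cps] <-
      sample(2:3, length(p_cps), replace = TRUE)
    p_beh <- i_vh[path == "behavior"]
    items$resists_care[p_beh] <- 1L
    items$physically_abusive[p_beh] <-
      sample(0:1, length(p_beh), replace = TRUE)
    # institutional risk: activate 3..5 of the static categories
    static <- c("prior_nursing_home", "homebound", "bladder_incontinence",
                "diagnosis", "bathing", "delirium", "meal_shopping")
    n_cat <- sample(3:5, k, replace = TRUE)
    for (j in seq_len(k)) {
      cats <- sample(static, n_cat[j])
      row <- i_vh[j]
      if ("prior_nursing_home" %in% cats) items$prior_nursing_home[row] <- 1L
      if ("homebound" %in% cats) items$goes_out[row] <- 0L
      if ("bladder_incontinence" %in% cats)
        items$bladder_incontinence[row] <- 1L
      if ("diagnosis" %in% cats) {
        dx_item <- sample(c("dx_dementia", "dx_alzheimers",
                            "dx_multiple_sclerosis", "dx_head_trauma"), 1)
        items[[dx_item]][row] <- 1L
      }
      if ("bathing" %in% cats) items$bathing_problem[row] <- 1L
      if ("delirium" %in% cats) {
        del_item <- sample(c("delirium_easily_distracted",
                             "delirium_disorganized_speech",
                             "delirium_mental_function_varies",
                             "delirium_acute_change"), 1)
        items[[del_item]][row] <- 1L
      }
      if ("meal_shopping" %in% cats) items$shopping_problem[row] <- 1L
    }
  }
  items
}

#' Inverse-construct item patterns for requested priority levels
#'
#' For each requested level, builds a 31-item assessment pattern that the
#' given tree maps back to exactly that level; the closed loop is verified
#' by re-scoring every constructed pattern, and any mismatch (a level with
#' no satisfying pattern under the active tree) is a hard error.
#'
#' Patterns are randomised within level-preserving bounds, so repeated
#' calls under one RNG stream vary; determinism comes from the caller's
#' seed.
#'
#' @param levels character vector of requested levels.
#' @param tree tree specification the patterns must satisfy.
#' @return data.frame of item columns, one row per requested level.
#' @export
inverse_construct_items <- function(levels, tree = default_tree_spec()) {
  bad <- setdiff(unique(as.character(levels)), maple_levels())
  if (length(bad) > 0)
    stop("unknown priority level(s): ", paste(bad, collapse = ", "))
  items <- construct_items(levels)
  risk <- institutional_risk(items, adl_declined = FALSE)
  v <- data.frame(
    adl = adl_hierarchy(items), cps = cps_score(items),
    behavior = behavior_disturbance(items),
    decision_decline = bool_item(items, "decision_making_decline"),
    medication_problem = bool_item(items, "medication_management_problem"),
    pressure_ulcer = bool_item(items, "pressure_ulcer"),
    fall = bool_item(items, "fall_recent"),
    meal_prep_problem = bool_item(items, "meal_preparation_problem"),
    swallowing_difficulty = bool_item(items, "swallowing_difficulty"),
    inst_risk_count = risk$count, inst_risk_active = risk$active,
    screener = geriatric_screener(items))
  got <- assign_priority(v, tree)
  if (!all(as.character(got) == as.character(levels))) {
    off <- which(as.character(got) != as.character(levels))[1]
    stop("generator/tree inconsistency: requested level '",
         as.character(levels)[off], "' scored as '",
         as.character(got)[off], "' under tree '", tree$version, "'")
  }
  items
}

## ---- cohort generation ----------------------------------------------------

empty_cohort <- function() {
  df <- as.data.frame(stats::setNames(
    rep(list(character(0)), length(cohort_column_order())),
    cohort_column_order()))
  maple_cohort(within(df, {
    days_to_event <- integer(0)
  }))
}

#' Generate a synthetic episode cohort
#'
#' Draws `n` episodes under a cohort profile: demographics and
#' per-timepoint priority levels from the profile marginals, item patterns
#' by inverse construction under `tree` (verified closed loop), the binary
#' discharge outcome from the profile's logistic outcome model, and — when
#' the profile carries a survival model — days to death as exponential
#' survival with covariate-dependent rate, censored at the profile's
#' censoring day. The one-year outcome is death if the episode died within
#' follow-up, otherwise drawn from the profile's conditional distribution
#' of residence among survivors.
#'
#' Reproducible: the same `(n, seed, profile, tree)` yields a
#' value-identical cohort. Provenance (seed, profile name, generating
#' model, tree version) is recorded in the `provenance` attribute.
#'
#' @param n number of episodes.
#' @param seed integer seed for the single RNG stream (Mersenne-Twister).
#' @param profile a [nordic_profile()] / [canadian_profile()] or compatible
#'   parameter list.
#' @param tree tree specification used for inverse construction.
#' @return a [maple_cohort()] with `provenance` attribute.
#' @export
#' @examples
#' coh <- generate_cohort(50, seed = 1)
#' table(score_cohort(coh)$level[score_cohort(coh)$timepoint == "premorbid"])
generate_cohort <- function(n, seed, profile = nordic_profile(),
                            tree = default_tree_spec()) {
  validate_profile(profile)
  stopifnot(n >= 0, length(n) == 1)
  if (n == 0) {
    out <- empty_cohort()
    attr(out, "provenance") <- list(n = 0L, seed = seed,
                                    profile = profile$name,
                                    tree_version = tree$version)
    return(out)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  patient_id <- sprintf("P%07d", seq_len(n))
  demo <- profile$demo
  sex <- sample(c("woman", "man"), n, replace = TRUE,
                prob = c(demo$p_woman, 1 - demo$p_woman))
  age_group <- sample(names(demo$p_age), n, replace = TRUE,
                      prob = demo$p_age)
  lived_alone <- stats::runif(n) < demo$p_lived_alone
  prior_hosp <- stats::runif(n) < demo$p_prior_hosp
  reason <- sample(names(demo$p_reason), n, replace = TRUE,
                   prob = demo$p_reason)
  dx <- sapply(names(profile$dx_prevalence), function(cc)
    stats::runif(n) < profile$dx_prevalence[cc])
  if (n == 1) dx <- matrix(dx, nrow = 1,
                           dimnames = list(NULL, names(profile$dx_prevalence)))

  tp_levels <- lapply(stats::setNames(nm = maple_timepoints()), function(tp)
    sample(maple_levels(), n, replace = TRUE, prob = profile$levels[[tp]]))
  day7_present <- stats::runif(n) >= profile$day7_missing_rate

  ## outcome model
  om <- profile$outcome_model
  b0 <- solve_logistic_intercept(profile, om)
  lp <- linear_predictor(om$or, sex, age_group, reason,
                         tp_levels[[om$timepoint]])
  p_pos <- stats::plogis(b0 + lp)
  positive <- stats::runif(n) < p_pos
  adverse <- if (om$endpoint == "discharge_home") !positive else positive

  ## survival (when the profile has follow-up)
  sm <- profile$survival_model
  if (!is.null(sm)) {
    lambda0 <- solve_baseline_hazard(profile, sm)
    lp_s <- linear_predictor(sm$hr, sex, age_group, reason,
                             tp_levels[[sm$timepoint]], dx = dx)
    t_death <- stats::rexp(n, rate = lambda0 * exp(lp_s))
    event_died <- t_death <= sm$censor_day
    days_to_event <- as.integer(pmin(ceiling(t_death), sm$censor_day))
    days_to_event[days_to_event < 1L] <- 1L
  } else {
    event_died <- rep(FALSE, n)
    days_to_event <- rep(NA_integer_, n)
  }

  ## discharge outcome: the OTHER category is carved from the negative
  ## class of the generating endpoint, so refits of that endpoint are
  ## unaffected by its disposition
  q_other <- profile$other_rate / (1 - om$target_rate)
  is_other <- !positive & stats::runif(n) < q_other
  if (om$endpoint == "discharge_home") {
    dead_dis <- adverse & !is_other & event_died & days_to_event <= 28L
    discharge_outcome <- ifelse(!adverse, "home",
                         ifelse(is_other, "other",
                         ifelse(dead_dis, "dead", "institution")))
  } else {
    dead_dis <- adverse & event_died & days_to_event <= 28L
    discharge_outcome <- ifelse(is_other, "other",
                         ifelse(!adverse, "home",
                         ifelse(dead_dis, "dead", "institution")))
  }
  ## keep the invariant: an episode dead at discharge has died on follow-up
  if (is.null(sm)) {
    dead_rows <- discharge_outcome == "dead"
    event_died[dead_rows] <- TRUE
    days_to_event[dead_rows] <- sample(1:28, sum(dead_rows), replace = TRUE)
  }

  if (!is.null(profile$one_year)) {
    oy_alive <- sample(names(profile$one_year), n, replace = TRUE,
                       prob = profile$one_year)
    one_year_outcome <- ifelse(event_died, "dead", oy_alive)
  } else {
    one_year_outcome <- rep(NA_character_, n)
  }

  ## assessments: inverse construction per time point (closed loop checked
  ## on the assembled cohort below)
  rows <- list()
  for (tp in maple_timepoints()) {
    keep <- if (tp == "day7_discharge") day7_present else rep(TRUE, n)
    if (!any(keep)) next
    items <- construct_items(tp_levels[[tp]][keep])
    rows[[tp]] <- cbind(
      data.frame(patient_id = patient_id[keep], timepoint = tp,
                 sex = sex[keep], age_group = age_group[keep],
                 lived_alone = lived_alone[keep],
                 prior_hosp_90d = prior_hosp[keep],
                 reason = reason[keep],
                 dxgrp_neoplasms = dx[keep, "dxgrp_neoplasms"],
                 dxgrp_mental_behavioral = dx[keep, "dxgrp_mental_behavioral"],
                 dxgrp_respiratory = dx[keep, "dxgrp_respiratory"],
                 discharge_outcome = discharge_outcome[keep],
                 one_year_outcome = one_year_outcome[keep],
                 days_to_event = days_to_event[keep],
                 event_died = event_died[keep]),
      items)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$patient_id, match(df$timepoint, maple_timepoints())), ]
  cohort <- maple_cohort(df)

  ## closed-loop guarantee: every constructed assessment scores the level
  ## it was generated for
  scored <- score_cohort(cohort, tree)
  for (tp in maple_timepoints()) {
    got <- scored[scored$timepoint == tp, ]
    want <- tp_levels[[tp]][match(got$patient_id, patient_id)]
    if (!all(got$computable) ||
          !all(as.character(got$level) == want))
      stop("generator/tree inconsistency at time point '", tp,
           "' under tree '", tree$version, "'")
  }

  attr(cohort, "provenance") <- list(
    n = as.integer(n), seed = seed, profile = profile$name,
    outcome_model = om$timepoint, endpoint = om$endpoint,
    tree_version = tree$version,
    generated = list(levels = tp_levels))
  cohort
}
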