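## The analytic battery: binary-endpoint logistic models with odds ratios,
## pseudo R-squared and c-statistics; ROC curves; Cox proportional-hazards
## models for days to death; cohort cross-tabulations; and report tables.

#' Endpoint specifications for the binary outcome models
#'
#' Maps each outcome category to positive / negative / excluded for one of
#' the four analysed endpoints. The disposition of the `other` category is
#' configurable; by default it is counted negative for the "home" endpoints
#' and excluded for the adverse endpoints (matching the varying printed
#' denominators). The reference priority level is `very_high` for home
#' endpoints and `low` for adverse endpoints.
#'
#' @param name one of `discharged_home`, `adverse_at_discharge`,
#'   `home_at_one_year`, `adverse_at_one_year`.
#' @param other disposition of the `other` outcome category.
#' @return list with `name`, `field` (outcome column), `disposition`
#'   (named vector over the outcome categories), `reference_level`.
#' @export
endpoint_spec <- function(name = c("discharged_home", "adverse_at_discharge",
                                   "home_at_one_year", "adverse_at_one_year"),
                          other = NULL) {
  name <- match.arg(name)
  home_like <- name %in% c("discharged_home", "home_at_one_year")
  disposition <- if (home_like) {
    c(home = "positive", institution = "negative", dead = "negative",
      other = "negative")
  } else {
    c(home = "negative", institution = "positive", dead = "positive",
      other = "excluded")
  }
  if (!is.null(other)) {
    stopifnot(other %in% c("positive", "negative", "excluded"))
    disposition["other"] <- other
  }
  list(name = name,
       field = if (grepl("one_year", name)) "one_year_outcome" else
         "discharge_outcome",
       disposition = disposition,
       reference_level = if (home_like) "very_high" else "low")
}

## one row per episode (episode-level fields from the pre-morbid row)
episode_table <- function(cohort) {
  df <- as.data.frame(cohort)
  df <- df[!duplicated(df$patient_id), episode_columns(), drop = FALSE]
  rownames(df) <- NULL
  df
}

## dummy-coded model frame shared by the logistic and Cox fits
model_frame <- function(cohort, at, tree, reference_level, ...) {
  ep <- episode_table(cohort)
  scored <- score_cohort(cohort, tree, ...)
  scored <- scored[scored$timepoint == at & scored$computable, , drop = FALSE]
  idx <- match(ep$patient_id, scored$patient_id)
  ep$level <- as.character(scored$level)[idx]
  ep <- ep[!is.na(ep$level), , drop = FALSE]
  ep$sex <- factor(ep$sex, levels = c("man", "woman"))
  ep$age_group <- factor(ep$age_group,
                         levels = c("75_79", "80_84", "85_89", "90_plus"))
  ep$reason <- factor(ep$reason,
                      levels = c("new_problem", "exacerbation", "both"))
  ep$level <- factor(ep$level, levels = c(reference_level,
                                          setdiff(maple_levels(),
                                                  reference_level)))
  ep
}

term_label <- function(covariate, lev) {
  pretty <- c(sex = "sex", age_group = "age", reason = "reason",
              level = "maple_ac",
              dxgrp_neoplasms = "dx_neoplasms",
              dxgrp_mental_behavioral = "dx_mental_behavioral",
              dxgrp_respiratory = "dx_respiratory")
  unname(pretty[covariate])
}

## coefficient table with reference rows marked estimate 1.00 (no CI)
build_terms <- function(coefs, ses, pvals, frame, covariates) {
  out <- list()
  for (cv in covariates) {
    if (is.factor(frame[[cv]])) {
      levs <- levels(frame[[cv]])
      for (i in seq_along(levs)) {
        cname <- paste0(cv, levs[i])
        if (i == 1) {
          out[[length(out) + 1]] <- data.frame(
            covariate = cv, level = levs[i], estimate = 1.00,
            ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
            is_reference = TRUE)
        } else if (cname %in% names(coefs)) {
          b <- coefs[cname]; s <- ses[cname]
          out[[length(out) + 1]] <- data.frame(
            covariate = cv, level = levs[i], estimate = exp(b),
            ci_low = exp(b - stats::qnorm(0.975) * s),
            ci_high = exp(b + stats::qnorm(0.975) * s),
            p_value = pvals[cname], is_reference = FALSE)
        }
      }
    } else {  # 0/1 covariate
      cname <- if (cv %in% names(coefs)) cv else paste0(cv, "TRUE")
      b <- coefs[cname]; s <- ses[cname]
      out[[length(out) + 1]] <- data.frame(
        covariate = cv, level = "yes", estimate = exp(b),
        ci_low = exp(b - stats::qnorm(0.975) * s),
        ci_high = exp(b + stats::qnorm(0.975) * s),
        p_value = pvals[cname], is_reference = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

check_separation <- function(coefs, ses, kind) {
  bad <- names(coefs)[!is.na(coefs) &
                        (abs(coefs) > 15 | (!is.na(ses) & ses > 50))]
  bad <- setdiff(bad, "(Intercept)")
  if (length(bad) > 0)
    stop(kind, " fit shows (quasi-)complete separation / monotone ",
         "likelihood for: ", paste(bad, collapse = ", "))
}

#' Fit a multivariate logistic endpoint model
#'
#' Logistic regression of one binary endpoint on sex, age group (dummy,
#' reference 75-79), reason for hospitalisation (reference: new problem)
#' and the priority level at one assessment time point (reference per
#' endpoint). Reports odds ratios with 95% Wald confidence intervals on
#' the log scale, both pseudo R-squared variants (unscaled Cox-Snell and
#' max-rescaled Nagelkerke), and the c-statistic of the fitted
#' probabilities.
#'
#' @param cohort a [maple_cohort()].
#' @param endpoint an [endpoint_spec()].
#' @param at assessment time point whose priority level enters the model.
#' @param tree tree specification used to score the cohort.
#' @return a `maple_model` result: `terms` (OR, CI, p, reference rows with
#'   estimate 1.00), `pseudo_r2` (unscaled, max_rescaled), `c_statistic`,
#'   `n_positive`, `n_negative`, `model_kind = "logistic"`, provenance.
#' @export
fit_logistic <- function(cohort, endpoint = endpoint_spec("discharged_home"),
                         at = "premorbid", tree = default_tree_spec()) {
  frame <- model_frame(cohort, at, tree, endpoint$reference_level)
  disp <- endpoint$disposition[frame[[endpoint$field]]]
  keep <- !is.na(disp) & disp != "excluded"
  frame <- frame[keep, , drop = FALSE]
  y <- disp[keep] == "positive"
  if (sum(y) == 0 || sum(!y) == 0)
    stop("endpoint '", endpoint$name, "' has a single outcome class (",
         sum(y), " positive / ", sum(!y), " negative)")
  frame$.y <- y
  fit <- stats::glm(.y ~ sex + age_group + reason + level,
                    family = stats::binomial(), data = frame)
  sm <- summary(fit)
  coefs <- stats::coef(fit)
  ses <- sm$coefficients[, "Std. Error"][names(coefs)]
  pvals <- sm$coefficients[, "Pr(>|z|)"][names(coefs)]
  check_separation(coefs, ses, "logistic")

  n <- nrow(frame)
  lr <- fit$null.deviance - fit$deviance
  r2_cs <- 1 - exp(-lr / n)
  r2_max <- 1 - exp(-fit$null.deviance / n)
  roc <- roc_auc(stats::fitted(fit), y)

  structure(list(
    terms = build_terms(coefs, ses, pvals, frame,
                        c("sex", "age_group", "reason", "level")),
    pseudo_r2 = c(unscaled = r2_cs, max_rescaled = r2_cs / r2_max),
    c_statistic = roc$auc,
    n_positive = sum(y), n_negative = sum(!y),
    model_kind = "logistic", endpoint = endpoint$name, timepoint = at,
    reference_level = endpoint$reference_level,
    tree_version = tree$version),
    class = "maple_model")
}

#' ROC curve and AUC by trapezoidal integration
#'
#' Builds the ROC curve over all distinct score thresholds and integrates
#' it with the trapezoid rule, which equals the Mann-Whitney concordance
#' probability with ties counted one half. Rank-invariant: any strictly
#' increasing transform of the scores leaves the curve unchanged.
#'
#' @param score numeric risk scores (higher = more likely positive).
#' @param outcome logical (or 0/1) outcomes.
#' @return a `maple_roc`: `points` data.frame (`fpr`, `tpr`) from (0,0) to
#'   (1,1), and `auc`.
#' @export
roc_auc <- function(score, outcome) {
  outcome <- as.logical(outcome)
  stopifnot(length(score) == length(outcome), !anyNA(score),
            !anyNA(outcome))
  n_pos <- sum(outcome); n_neg <- sum(!outcome)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC requires at least one positive and one negative outcome")
  o <- order(score, decreasing = TRUE)
  s <- score[o]; y <- outcome[o]
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(s, fromLast = TRUE)  # one point per distinct threshold
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "maple_roc")
}

#' @export
print.maple_roc <- function(x, ...) {
  cat("ROC curve:", nrow(x$points), "points, AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Fit a Cox proportional-hazards model for days to death
#'
#' Cox regression of days to death (censored at 365) on sex, age group,
#' reason for hospitalisation, the priority level at one time point
#' (reference: low) and the three ICD-10 diagnosis-group flags (neoplasms;
#' mental and behavioural; respiratory). Ties are handled by the Efron
#' approximation by default (day granularity guarantees ties); Breslow is
#' available via `ties`.
#'
#' @inheritParams fit_logistic
#' @param ties tie-handling method passed to [survival::coxph()].
#' @return a `maple_model` with hazard ratios (`model_kind = "cox"`).
#' @export
fit_cox <- function(cohort, at = "premorbid", tree = default_tree_spec(),
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  frame <- model_frame(cohort, at, tree, "low")
  frame <- frame[!is.na(frame$days_to_event) & !is.na(frame$event_died), ,
                 drop = FALSE]
  if (sum(frame$event_died) == 0)
    stop("no death events in cohort; cannot fit a survival model")
  for (cc in c("dxgrp_neoplasms", "dxgrp_mental_behavioral",
               "dxgrp_respiratory"))
    frame[[cc]] <- as.integer(frame[[cc]])
  fit <- survival::coxph(
    survival::Surv(days_to_event, event_died) ~ sex + age_group + reason +
      level + dxgrp_neoplasms + dxgrp_mental_behavioral + dxgrp_respiratory,
    data = frame, ties = ties)
  sm <- summary(fit)
  coefs <- stats::coef(fit)
  ses <- sm$coefficients[, "se(coef)"][names(coefs)]
  pvals <- sm$coefficients[, "Pr(>|z|)"][names(coefs)]
  check_separation(coefs, ses, "Cox")

  structure(list(
    terms = build_terms(coefs, ses, pvals, frame,
                        c("sex", "age_group", "reason", "level",
                          "dxgrp_neoplasms", "dxgrp_mental_behavioral",
                          "dxgrp_respiratory")),
    pseudo_r2 = c(unscaled = NA_real_, max_rescaled = NA_real_),
    c_statistic = unname(sm$concordance["C"]),
    n_positive = sum(frame$event_died),
    n_negative = sum(!frame$event_died),
    model_kind = "cox", endpoint = "days_to_death", timepoint = at,
    reference_level = "low", ties = ties,
    tree_version = tree$version),
    class = "maple_model")
}

#' @export
print.maple_model <- function(x, ...) {
  lab <- if (x$model_kind == "logistic") "OR" else "HR"
  cat(sprintf("%s model: %s at %s (%d positive / %d negative)\n",
              x$model_kind, x$endpoint, x$timepoint, x$n_positive,
              x$n_negative))
  t <- x$terms
  est <- ifelse(t$is_reference, "1.00 (ref)",
                sprintf("%.2f (%.2f-%.2f)", t$estimate, t$ci_low, t$ci_high))
  cat(sprintf("  %-26s %s = %s\n",
              paste(t$covariate, t$level), lab, est), sep = "")
  if (!is.na(x$pseudo_r2["unscaled"]))
    cat(sprintf("  R-square %.1f%% (max-rescaled %.1f%%)\n",
                100 * x$pseudo_r2["unscaled"],
                100 * x$pseudo_r2["max_rescaled"]))
  cat(sprintf("  c-statistic %.3f\n", x$c_statistic))
  invisible(x)
}

#' Compare two cohorts on a categorical variable
#'
#' Pearson chi-squared test (no continuity correction) on the observed
#' contingency table of episode counts by category; degrees of freedom
#' (r-1)(c-1). Categories unused by both cohorts are dropped; any
#' remaining zero expected count is an error with the table attached.
#'
#' @param a,b two [maple_cohort()]s.
#' @param variable episode-level categorical column to compare.
#' @return list: `statistic`, `df`, `p_value`, `table`.
#' @export
crosstab_compare <- function(a, b, variable) {
  va <- episode_table(a)[[variable]]
  vb <- episode_table(b)[[variable]]
  if (length(va) == 0 || length(vb) == 0) stop("both cohorts must be non-empty")
  lev <- sort(unique(c(va, vb)))
  tab <- rbind(a = table(factor(va, levels = lev)),
               b = table(factor(vb, levels = lev)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0))
    stop("zero expected cell count in contingency table:\n",
         paste(utils::capture.output(print(tab)), collapse = "\n"))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), table = tab)
}

#' Collect model results into report tables
#'
#' Flattens fitted models into one tidy table mirroring the published
#' layout: one row per term with OR/HR, CI, reference rows carrying
#' estimate 1.00, plus per-model pseudo R-squared (as %), c-statistic,
#' class sizes and tree-version provenance. Written as CSV when `path` is
#' given; [read_model_report()] re-parses it value-identically.
#'
#' @param results list of `maple_model` objects.
#' @param path optional CSV output path.
#' @param seed optional seed to record as provenance.
#' @return the report data.frame, invisibly when written to `path`.
#' @export
report_tables <- function(results, path = NULL, seed = NA) {
  blocks <- lapply(results, function(m) {
    cbind(data.frame(model_kind = m$model_kind, endpoint = m$endpoint,
                     timepoint = m$timepoint),
          m$terms,
          data.frame(pseudo_r2_pct = 100 * m$pseudo_r2[["unscaled"]],
                     pseudo_r2_max_rescaled_pct =
                       100 * m$pseudo_r2[["max_rescaled"]],
                     c_statistic = m$c_statistic,
                     n_positive = m$n_positive, n_negative = m$n_negative,
                     tree_version = m$tree_version,
                     seed = seed))
  })
  report <- if (length(blocks) > 0) do.call(rbind, blocks) else
    data.frame(model_kind = character(), endpoint = character(),
               timepoint = character(), covariate = character(),
               level = character(), estimate = numeric(),
               ci_low = numeric(), ci_high = numeric(),
               p_value = numeric(), is_reference = logical(),
               pseudo_r2_pct = numeric(),
               pseudo_r2_max_rescaled_pct = numeric(),
               c_statistic = numeric(), n_positive = integer(),
               n_negative = integer(), tree_version = character(),
               seed = numeric())
  rownames(report) <- NULL
  if (!is.null(path)) {
    utils::write.csv(report, path, row.names = FALSE, na = "")
    return(invisible(report))
  }
  report
}

#' @rdname report_tables
#' @export
read_model_report <- function(path) {
  utils::read.csv(path, na.strings = "",
                  colClasses = c(tree_version = "character"))
}
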