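# Independent oracles, kept deliberately separate in structure from the
# production code: per-row transcriptions of the published scoring grids
# and a naive rule interpreter for the decision tree.

# Cognitive Performance Scale grid, one case at a time.
# eat is the raw eating self-performance code (8 = did not occur).
cps_oracle_one <- function(comatose, memory, decision, understood, eat) {
  if (comatose == 1) return(6L)
  eating_total <- eat %in% c(6, 8)
  if (decision == 3) {
    if (eating_total) return(6L) else return(5L)
  }
  n_impaired <- (decision >= 1) + (memory >= 1) + (understood >= 1)
  n_severe <- (decision >= 2) + (understood >= 2)
  if (n_impaired <= 1) return(c(0L, 1L)[n_impaired + 1])
  c(2L, 3L, 4L)[n_severe + 1]
}

# ADL hierarchy grid, one case at a time; raw codes (8 = did not occur,
# counted as total dependence).
adlh_oracle_one <- function(hygiene, toilet, locomotion, eating) {
  x <- c(hygiene, toilet, locomotion, eating)
  x[x == 8] <- 6
  late <- c(x[3], x[4])  # locomotion, eating
  if (all(x == 6)) return(6L)
  if (any(late == 6)) return(5L)
  if (any(late >= 4)) return(4L)
  if (any(x >= 4)) return(3L)
  if (any(x == 3)) return(2L)
  if (any(x == 2)) return(1L)
  0L
}

# Naive, recursive condition evaluator + first-match rule interpreter for
# tree specifications (test-only; the production engine is vectorised).
naive_eval_cond <- function(e, env) {
  if (is.name(e)) return(env[[as.character(e)]])
  if (is.atomic(e)) return(e)
  op <- as.character(e[[1]])
  if (op == "(") return(naive_eval_cond(e[[2]], env))
  if (op == "!") return(!naive_eval_cond(e[[2]], env))
  a <- naive_eval_cond(e[[2]], env)
  b <- naive_eval_cond(e[[3]], env)
  switch(op,
         "&" = , "&&" = a && b,
         "|" = , "||" = a || b,
         ">=" = a >= b, "<=" = a <= b, ">" = a > b, "<" = a < b,
         "==" = a == b, "!=" = a != b,
         stop("naive evaluator: unknown operator ", op))
}

naive_assign_one <- function(row, tree) {
  env <- as.list(row)
  for (r in tree$rules)
    if (isTRUE(naive_eval_cond(str2lang(r$condition), env)))
      return(r$level)
  tree$default_level
}

# All-pairs Mann-Whitney concordance with ties counted one half.
auc_pairwise_oracle <- function(score, outcome) {
  pos <- score[outcome]
  neg <- score[!outcome]
  total <- 0
  for (p in pos)
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Full discrete classifier grid (screener trimmed to its decision-relevant
# range); used for exhaustive tree properties.
classifier_grid <- function(screener_values = 0:2) {
  g <- expand.grid(adl = 0:6, cps = 0:6,
                   behavior = c(FALSE, TRUE),
                   decision_decline = c(FALSE, TRUE),
                   medication_problem = c(FALSE, TRUE),
                   pressure_ulcer = c(FALSE, TRUE),
                   fall = c(FALSE, TRUE),
                   meal_prep_problem = c(FALSE, TRUE),
                   swallowing_difficulty = c(FALSE, TRUE),
                   inst_risk_count = 0:8,
                   screener = screener_values,
                   KEEP.OUT.ATTRS = FALSE)
  g$inst_risk_active <- g$inst_risk_count >= 3
  g
}

# Assessment items that fire an exact set of the eight risk categories
# (decline is passed separately to institutional_risk()).
risk_category_items <- function(flags) {
  a <- intact_assessment_items()
  if (flags[1]) a$prior_nursing_home <- 1L
  if (flags[2]) a$goes_out <- 0L
  if (flags[3]) a$bladder_incontinence <- 1L
  if (flags[4]) a$dx_dementia <- 1L
  # flags[5] is the ADL-decline category, handled by the caller
  if (flags[6]) a$bathing_problem <- 1L
  if (flags[7]) a$delirium_acute_change <- 1L
  if (flags[8]) a$shopping_problem <- 1L
  a
}
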