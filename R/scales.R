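## Embedded subscales consumed by the decision tree. All functions are pure
## and vectorised: they accept one assessment (named list / one-row
## data.frame) or many (multi-row data.frame) and return one value per row.
## A missing scale-critical input yields NA ("non-computable"), never a
## numeric default; missing boolean flags are treated as "not present" with
## a warning (interRAI forms default binary flags to unchecked).

as_assessment_df <- function(a) {
  if (is.data.frame(a)) a else as.data.frame(as.list(a))
}

## boolean item under the two-tier missing policy (degraded tier)
bool_item <- function(a, code) {
  v <- if (code %in% names(a)) a[[code]] else rep(NA_integer_, nrow(a))
  n_na <- sum(is.na(v))
  if (n_na > 0)
    warning(sprintf("treating %d missing '%s' flag(s) as not present",
                    n_na, code), call. = FALSE)
  !is.na(v) & v > 0
}

int_item <- function(a, code) {
  if (code %in% names(a)) as.integer(a[[code]]) else
    rep(NA_integer_, nrow(a))
}

## ADL self-performance with the "activity did not occur" code (8) mapped
## to a configurable dependence level (standard convention: total
## dependence, 6).
adl_code <- function(a, code, did_not_occur = 6L) {
  v <- int_item(a, code)
  v[!is.na(v) & v == 8L] <- as.integer(did_not_occur)
  v
}

#' Cognitive Performance Scale (CPS)
#'
#' Ordinal 0 (intact) to 6 (very severe impairment), built from coma
#' status, short-term memory, daily decision-making, making self
#' understood, and eating self-performance. Coma dominates every other
#' item; severely impaired decision-making splits 5 vs 6 on total
#' dependence in eating.
#'
#' @param a assessment(s): named list or data.frame with item columns.
#' @param did_not_occur dependence level substituted for the ADL
#'   "activity did not occur" code (8) on the eating item.
#' @return integer vector in 0..6; NA where a required item is missing.
#' @export
#' @examples
#' cps_score(intact_assessment_items())
cps_score <- function(a, did_not_occur = 6L) {
  a <- as_assessment_df(a)
  com <- int_item(a, "comatose")
  mem <- int_item(a, "short_term_memory_problem")
  dec <- int_item(a, "decision_making")
  und <- int_item(a, "making_self_understood")
  eat <- adl_code(a, "adl_eating", did_not_occur)

  imp <- (dec >= 1L) + (mem >= 1L) + (und >= 1L)
  sev <- (dec >= 2L) + (und >= 2L)
  base <- ifelse(imp == 0L, 0L,
          ifelse(imp == 1L, 1L,
          ifelse(sev == 0L, 2L,
          ifelse(sev == 1L, 3L, 4L))))
  eat_total <- eat >= 6L
  out <- ifelse(com > 0L, 6L,
         ifelse(dec == 3L, ifelse(eat_total, 6L, 5L), base))
  out[is.na(com) | is.na(mem) | is.na(dec) | is.na(und) | is.na(eat)] <-
    NA_integer_
  as.integer(out)
}

#' ADL self-performance hierarchy
#'
#' Ordinal 0 (independent) to 6 (total dependence) over the four late-loss
#' activities of daily living: personal hygiene, toilet use, locomotion,
#' eating. The hierarchy weights the later-loss activities (eating,
#' locomotion) more heavily than the earlier-loss ones; the scale is
#' non-decreasing in every item's dependence code.
#'
#' @inheritParams cps_score
#' @return integer vector in 0..6; NA where any of the four items is missing.
#' @export
#' @examples
#' adl_hierarchy(intact_assessment_items())
adl_hierarchy <- function(a, did_not_occur = 6L) {
  a <- as_assessment_df(a)
  h <- adl_code(a, "adl_hygiene",    did_not_occur)
  t <- adl_code(a, "adl_toilet_use", did_not_occur)
  l <- adl_code(a, "adl_locomotion", did_not_occur)
  e <- adl_code(a, "adl_eating",     did_not_occur)
  m <- pmax(h, t, l, e)
  out <- ifelse(h == 6L & t == 6L & l == 6L & e == 6L, 6L,
         ifelse(e == 6L | l == 6L, 5L,
         ifelse(e >= 4L | l >= 4L, 4L,
         ifelse(m >= 4L, 3L,
         ifelse(m == 3L, 2L,
         ifelse(m == 2L, 1L, 0L))))))
  as.integer(out)
}

#' ADL decline between pre-morbid baseline and a later assessment
#'
#' TRUE iff the later ADL hierarchy score strictly exceeds the pre-morbid
#' one (decline is one-directional; improvement is not decline).
#'
#' @param premorbid,later assessments (rows aligned).
#' @inheritParams cps_score
#' @return logical vector; NA where either side is non-computable.
#' @export
adl_decline <- function(premorbid, later, did_not_occur = 6L) {
  adl_hierarchy(later, did_not_occur) >
    adl_hierarchy(premorbid, did_not_occur)
}

#' Behaviour-disturbance composite
#'
#' TRUE iff any of: verbally abusive, physically abusive, socially
#' inappropriate behaviour, resists care. Missing flags count as not
#' present (with a warning).
#'
#' @inheritParams cps_score
#' @return logical vector.
#' @export
behavior_disturbance <- function(a) {
  a <- as_assessment_df(a)
  bool_item(a, "verbally_abusive") | bool_item(a, "physically_abusive") |
    bool_item(a, "socially_inappropriate") | bool_item(a, "resists_care")
}

#' Institutional (nursing-home) risk screener
#'
#' A count over 8 risk categories: prior nursing-home placement; not going
#' out (homebound); bladder incontinence; a qualifying diagnosis (any
#' dementia, Alzheimer's disease, multiple sclerosis, head trauma); ADL
#' decline; hygiene or bathing problem; indicators of delirium; meal
#' preparation and shopping problems. In the acute-care algorithm the risk
#' flag is active at 3 or more categories (the home-care cut-off is 4).
#'
#' ADL decline is computed across time points and is therefore an argument
#' here; at the pre-morbid time point it is FALSE by definition (no earlier
#' baseline exists). The "going out" polarity is risk-when-homebound by
#' default, overridable via `homebound_is_risk`.
#'
#' @inheritParams cps_score
#' @param adl_declined logical vector (recycled): the cross-timepoint ADL
#'   decline category.
#' @param homebound_is_risk if TRUE (default) the category fires when the
#'   person did not go out.
#' @param cutoff activation threshold on the category count (default 3).
#' @return data.frame with integer `count` (0..8) and logical `active`.
#' @export
institutional_risk <- function(a, adl_declined = FALSE,
                               homebound_is_risk = TRUE, cutoff = 3L,
                               did_not_occur = 6L) {
  a <- as_assessment_df(a)
  n <- nrow(a)
  adl_declined <- rep_len(!is.na(adl_declined) & adl_declined, n)

  goes_out <- if ("goes_out" %in% names(a)) a[["goes_out"]] else
    rep(NA_integer_, n)
  homebound <- if (homebound_is_risk) {
    !is.na(goes_out) & goes_out == 0L
  } else {
    !is.na(goes_out) & goes_out > 0L
  }
  hygiene_code <- adl_code(a, "adl_hygiene", did_not_occur)
  hygiene_bad <- !is.na(hygiene_code) & hygiene_code >= 4L

  cats <- cbind(
    prior_nursing_home = bool_item(a, "prior_nursing_home"),
    homebound          = homebound,
    bladder            = bool_item(a, "bladder_incontinence"),
    diagnosis          = bool_item(a, "dx_dementia") |
                         bool_item(a, "dx_alzheimers") |
                         bool_item(a, "dx_multiple_sclerosis") |
                         bool_item(a, "dx_head_trauma"),
    adl_decline        = adl_declined,
    hygiene_bathing    = bool_item(a, "bathing_problem") | hygiene_bad,
    delirium           = bool_item(a, "delirium_easily_distracted") |
                         bool_item(a, "delirium_disorganized_speech") |
                         bool_item(a, "delirium_mental_function_varies") |
                         bool_item(a, "delirium_acute_change"),
    meal_shopping      = bool_item(a, "meal_preparation_problem") |
                         bool_item(a, "shopping_problem")
  )
  count <- as.integer(rowSums(cats))
  data.frame(count = count, active = count >= as.integer(cutoff))
}

#' Geriatric screener subscore
#'
#' Count of screener findings among: short-term memory problem, impaired
#' daily decision-making, medication-management problem, meal-preparation
#' problem. The home-care screener's stamina item has no acute-care
#' counterpart and is excluded by construction, so stamina-like inputs
#' never influence the score.
#'
#' @inheritParams cps_score
#' @return integer vector (0..4); NA where a cognition input is missing.
#' @export
geriatric_screener <- function(a) {
  a <- as_assessment_df(a)
  mem <- int_item(a, "short_term_memory_problem")
  dec <- int_item(a, "decision_making")
  score <- (mem >= 1L) + (dec >= 1L) +
    bool_item(a, "medication_management_problem") +
    bool_item(a, "meal_preparation_problem")
  as.integer(score)
}

#' A fully intact assessment item pattern
#'
#' All 31 crosswalk items at their no-impairment value; useful as a test
#' and documentation baseline (scores CPS 0, ADL hierarchy 0, risk count 0,
#' priority low). `goes_out = 1` (the person goes out) so the homebound
#' risk category does not fire.
#'
#' @return one-row data.frame with all item columns.
#' @export
intact_assessment_items <- function() {
  a <- as.data.frame(as.list(stats::setNames(rep(0L, 31L), item_codes())))
  a$goes_out <- 1L
  a
}
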