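#' @keywords internal
"_PACKAGE"

## Controlled vocabularies used throughout the package. Values are stored
## lower-case in episode tables and CSV files.

#' Assessment time points of an acute-care episode
#'
#' The instrument collects a pre-morbid status (30 days before admission),
#' an admission status (the 24 hours prior to admission) and a third status
#' 24 hours pre-discharge or on day 7, whichever comes first. The ordering
#' is chronological.
#'
#' @return Character vector of the three time-point codes, in order.
#' @export
#' @examples
#' maple_timepoints()
maple_timepoints <- function() {
  c("premorbid", "admission", "day7_discharge")
}

#' The five priority levels, in increasing order of priority
#'
#' @return Character vector of the five level codes, ordered low to very high.
#' @export
#' @examples
#' maple_levels()
maple_levels <- function() {
  c("low", "mild", "moderate", "high", "very_high")
}

#' @rdname maple_levels
#' @param x character vector of level codes.
#' @return `maple_level_factor()` returns `x` as an ordered factor over the
#'   five levels.
#' @export
maple_level_factor <- function(x) {
  factor(x, levels = maple_levels(), ordered = TRUE)
}

## Episode-level (per patient) columns and their domains.
## The dxgrp_* flags are ICD-10 chapter groups used as covariates in the
## survival models (neoplasms; mental and behavioural; respiratory); they
## are episode-level diagnoses, not crosswalk items.
episode_columns <- function() {
  c("patient_id", "sex", "age_group", "lived_alone", "prior_hosp_90d",
    "reason", "dxgrp_neoplasms", "dxgrp_mental_behavioral",
    "dxgrp_respiratory", "discharge_outcome", "one_year_outcome",
    "days_to_event", "event_died")
}

episode_logical_columns <- function() {
  c("lived_alone", "prior_hosp_90d", "dxgrp_neoplasms",
    "dxgrp_mental_behavioral", "dxgrp_respiratory", "event_died")
}

episode_enum_domains <- function() {
  list(
    sex              = c("woman", "man"),
    age_group        = c("75_79", "80_84", "85_89", "90_plus"),
    reason           = c("new_problem", "exacerbation", "both"),
    discharge_outcome = c("home", "institution", "dead", "other"),
    one_year_outcome  = c("home", "institution", "dead", "other")
  )
}

#' The 31-item crosswalk map
#'
#' The acute-care algorithm is a crosswalk of a 44-item home-care
#' algorithm; only 31 items are directly available on the acute-care
#' instrument. This table enumerates them: the item code, its value domain,
#' the item group, and the subscales/classifiers that consume it.
#' Diagnosis and delirium indicators are stored as their raw instrument
#' items; the composite risk categories (any qualifying diagnosis, any
#' delirium indicator) are derived at scoring time.
#'
#' Value domains: `adl` = self-performance 0--6 plus 8 ("activity did not
#' occur"); `scale3` = 0--3; `binary` = 0/1.
#'
#' @return A data.frame with columns `item_code`, `group`, `domain`,
#'   `consumers` (semicolon-separated classifier names).
#' @export
#' @examples
#' nrow(maple_item_map())  # 31 crosswalk items
maple_item_map <- function() {
  im <- rbind(
    data.frame(item_code = c("adl_hygiene", "adl_toilet_use",
                             "adl_locomotion", "adl_eating"),
               group = "adl", domain = "adl",
               consumers = c("adl_hierarchy;institutional_risk",
                             "adl_hierarchy", "adl_hierarchy",
                             "adl_hierarchy;cps")),
    data.frame(item_code = c("comatose", "short_term_memory_problem",
                             "decision_making", "making_self_understood"),
               group = "cognition",
               domain = c("binary", "binary", "scale3", "scale3"),
               consumers = c("cps", "cps;geriatric_screener",
                             "cps;geriatric_screener", "cps")),
    data.frame(item_code = c("verbally_abusive", "physically_abusive",
                             "socially_inappropriate", "resists_care"),
               group = "behavior", domain = "binary",
               consumers = "behavior_disturbance"),
    data.frame(item_code = c("decision_making_decline",
                             "medication_management_problem",
                             "pressure_ulcer", "fall_recent",
                             "meal_preparation_problem",
                             "swallowing_difficulty"),
               group = "clinical", domain = "binary",
               consumers = c("tree", "tree;geriatric_screener", "tree",
                             "tree", "tree;geriatric_screener;institutional_risk",
                             "tree")),
    data.frame(item_code = c("prior_nursing_home", "goes_out",
                             "bladder_incontinence",
                             "dx_dementia", "dx_alzheimers",
                             "dx_multiple_sclerosis", "dx_head_trauma",
                             "bathing_problem",
                             "delirium_easily_distracted",
                             "delirium_disorganized_speech",
                             "delirium_mental_function_varies",
                             "delirium_acute_change",
                             "shopping_problem"),
               group = "risk", domain = "binary",
               consumers = "institutional_risk")
  )
  rownames(im) <- NULL
  im
}

item_codes <- function() maple_item_map()$item_code

## Value domain of one item as an integer vector (excludes the missing
## sentinel, which is NA / empty CSV field).
item_domain_values <- function(domain) {
  switch(domain,
         adl    = c(0:6, 8L),
         scale3 = 0:3,
         binary = 0:1,
         stop("unknown item domain: ", domain))
}

## Items whose absence makes a core scale non-computable (two-tier missing
## data policy): the four ADL items and the four cognition items. All
## boolean clinical/risk flags default to "not present" with a warning.
scale_critical_items <- function() {
  im <- maple_item_map()
  im$item_code[im$group %in% c("adl", "cognition")]
}

#' Write the machine-readable codebook
#'
#' Writes the item map plus episode-column domains as a two-section CSV
#' (section column distinguishes `item` and `episode` rows). The shipped
#' copy lives at `system.file("extdata", "codebook.csv", package = "mapleAC")`.
#'
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(path) {
  im <- maple_item_map()
  item_rows <- data.frame(section = "item", code = im$item_code,
                          group = im$group, domain = im$domain,
                          values = vapply(im$domain, function(d)
                            paste(item_domain_values(d), collapse = "|"), ""),
                          consumers = im$consumers)
  dom <- episode_enum_domains()
  ep <- data.frame(section = "episode", code = episode_columns(),
                   group = "episode",
                   domain = ifelse(episode_columns() %in% names(dom), "enum",
                                   ifelse(episode_columns() %in%
                                            episode_logical_columns(),
                                          "binary",
                                          ifelse(episode_columns() == "days_to_event",
                                                 "integer", "string"))),
                   values = vapply(episode_columns(), function(cc)
                     if (cc %in% names(dom)) paste(dom[[cc]], collapse = "|") else "",
                     ""),
                   consumers = "")
  utils::write.csv(rbind(item_rows, ep), path, row.names = FALSE)
  invisible(path)
}
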