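## The priority-assignment decision tree. The branch structure is shipped
## as a declarative, overridable rule table (YAML); rules are ordered
## highest severity first and evaluated first-match-wins with a default
## level, so the rule set is total by construction.

classifier_vector_fields <- function() {
  c("adl", "cps", "behavior", "decision_decline", "medication_problem",
    "pressure_ulcer", "fall", "meal_prep_problem", "swallowing_difficulty",
    "inst_risk_count", "inst_risk_active", "screener")
}

## classifier (scale) behind each vector field, for registry checks
vector_field_classifiers <- function() {
  c(adl = "adl_hierarchy", cps = "cps", behavior = "behavior_disturbance",
    decision_decline = "tree", medication_problem = "tree",
    pressure_ulcer = "tree", fall = "tree", meal_prep_problem = "tree",
    swallowing_difficulty = "tree", inst_risk_count = "institutional_risk",
    inst_risk_active = "institutional_risk", screener = "geriatric_screener")
}

allowed_condition_calls <- function() {
  c("&", "|", "!", "(", ">=", "<=", ">", "<", "==", "!=", "&&", "||")
}

check_condition_ast <- function(e, rule_name) {
  if (is.name(e)) {
    nm <- as.character(e)
    if (!nm %in% c(classifier_vector_fields(), "TRUE", "FALSE", "T", "F"))
      stop("rule '", rule_name, "': unknown field '", nm, "'")
  } else if (is.atomic(e)) {
    if (!(is.numeric(e) || is.logical(e)))
      stop("rule '", rule_name, "': literal must be numeric or logical")
  } else if (is.call(e)) {
    fn <- as.character(e[[1]])
    if (!fn %in% allowed_condition_calls())
      stop("rule '", rule_name, "': operator '", fn,
           "' not allowed in tree conditions")
    for (i in seq_along(e)[-1]) check_condition_ast(e[[i]], rule_name)
  } else {
    stop("rule '", rule_name, "': malformed condition")
  }
  invisible(TRUE)
}

parse_condition <- function(text, rule_name) {
  e <- tryCatch(str2lang(text),
                error = function(err) stop("rule '", rule_name,
                                           "': cannot parse condition: ",
                                           conditionMessage(err)))
  check_condition_ast(e, rule_name)
  e
}

#' Load a tree specification
#'
#' Reads a YAML tree specification (version string, default level, ordered
#' rule list) and validates it completely at load time: known levels, unique
#' rule names, and conditions restricted to comparisons and boolean algebra
#' over the classifier-vector fields. A malformed specification fails here,
#' never at scoring time.
#'
#' @param path path to a YAML tree file.
#' @return a `maple_tree` object.
#' @export
load_tree_spec <- function(path) {
  if (!file.exists(path)) stop("no such tree file: ", path)
  raw <- yaml::read_yaml(path)
  for (field in c("version", "default_level", "rules"))
    if (is.null(raw[[field]]))
      stop("tree spec is missing required field '", field, "'")
  if (!raw$default_level %in% maple_levels())
    stop("unknown default_level '", raw$default_level, "'")
  if (length(raw$rules) == 0) stop("tree spec has no rules")
  rules <- lapply(raw$rules, function(r) {
    for (field in c("name", "level", "condition"))
      if (is.null(r[[field]]))
        stop("tree rule is missing field '", field, "'")
    if (!r$level %in% maple_levels())
      stop("rule '", r$name, "': unknown level '", r$level, "'")
    list(name = r$name, level = r$level,
         condition = r$condition,
         expr = parse_condition(r$condition, r$name))
  })
  nm <- vapply(rules, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate rule names in tree spec")
  structure(list(version = as.character(raw$version),
                 default_level = raw$default_level, rules = rules),
            class = "maple_tree")
}

#' @rdname load_tree_spec
#' @return `default_tree_spec()` returns the reference tree shipped with
#'   the package.
#' @export
default_tree_spec <- function() {
  load_tree_spec(system.file("extdata", "tree_default.yaml",
                             package = "mapleAC", mustWork = TRUE))
}

#' @export
print.maple_tree <- function(x, ...) {
  cat("maple_tree '", x$version, "': ", length(x$rules),
      " rules, default level '", x$default_level, "'\n", sep = "")
  for (r in x$rules)
    cat(sprintf("  %-10s <- %s\n", r$level, r$condition))
  invisible(x)
}

#' Classifier vector for a cohort at one time point
#'
#' Computes every subscale the tree consumes for each episode's assessment
#' at `at`. The ADL-decline risk category compares against the pre-morbid
#' baseline; at the pre-morbid time point it is FALSE by definition.
#' Episodes whose scale-critical items (or pre-morbid baseline, for later
#' time points) are missing are returned with `computable = FALSE` and the
#' blocking classifier named, never silently dropped.
#'
#' @param cohort a [maple_cohort()].
#' @param at one of [maple_timepoints()].
#' @param homebound_is_risk,risk_cutoff,did_not_occur scale options passed
#'   through to [institutional_risk()] / [adl_hierarchy()].
#' @return data.frame: `patient_id`, the classifier fields
#'   (`adl`, `cps`, `behavior`, `decision_decline`, `medication_problem`,
#'   `pressure_ulcer`, `fall`, `meal_prep_problem`, `swallowing_difficulty`,
#'   `inst_risk_count`, `inst_risk_active`, `screener`), plus `computable`
#'   and `blocking`.
#' @export
classifier_vector <- function(cohort, at, homebound_is_risk = TRUE,
                              risk_cutoff = 3L, did_not_occur = 6L) {
  stopifnot(at %in% maple_timepoints())
  rows <- cohort[cohort$timepoint == at, , drop = FALSE]
  n <- nrow(rows)
  if (at == "premorbid") {
    decline <- rep(FALSE, n)
  } else {
    pre <- cohort[cohort$timepoint == "premorbid", , drop = FALSE]
    idx <- match(rows$patient_id, pre$patient_id)
    pre_aligned <- pre[idx, , drop = FALSE]
    decline <- adl_decline(pre_aligned, rows, did_not_occur)
  }
  risk <- institutional_risk(rows, adl_declined = decline,
                             homebound_is_risk = homebound_is_risk,
                             cutoff = risk_cutoff,
                             did_not_occur = did_not_occur)
  v <- data.frame(
    patient_id = rows$patient_id,
    adl = adl_hierarchy(rows, did_not_occur),
    cps = cps_score(rows, did_not_occur),
    behavior = behavior_disturbance(rows),
    decision_decline = bool_item(rows, "decision_making_decline"),
    medication_problem = bool_item(rows, "medication_management_problem"),
    pressure_ulcer = bool_item(rows, "pressure_ulcer"),
    fall = bool_item(rows, "fall_recent"),
    meal_prep_problem = bool_item(rows, "meal_preparation_problem"),
    swallowing_difficulty = bool_item(rows, "swallowing_difficulty"),
    inst_risk_count = risk$count,
    inst_risk_active = risk$active,
    screener = geriatric_screener(rows))

  blocking <- rep(NA_character_, n)
  blocking[is.na(v$adl)] <- "adl_hierarchy"
  blocking[is.na(v$cps)] <- "cps"
  blocking[is.na(v$screener) & is.na(blocking)] <- "geriatric_screener"
  if (at != "premorbid")
    blocking[is.na(decline) & is.na(blocking)] <- "adl_decline"
  v$computable <- is.na(blocking)
  v$blocking <- blocking
  v
}

#' Assign a priority level to classifier vectors
#'
#' Evaluates the tree's rules in order, first-match-wins; vectors matching
#' no rule receive the default level. Deterministic and total: every
#' complete vector maps to exactly one of the five levels, and only the
#' vector and the tree influence the result.
#'
#' @param v data.frame of classifier-vector fields (as from
#'   [classifier_vector()], or any data.frame with those columns).
#' @param tree a `maple_tree` (default: the shipped reference tree).
#' @return ordered factor over [maple_levels()], one per row of `v`.
#' @export
#' @examples
#' v <- classifier_vector_of_intact()
#' assign_priority(v)  # low
assign_priority <- function(v, tree = default_tree_spec()) {
  stopifnot(inherits(tree, "maple_tree"))
  v <- as.data.frame(v)
  used <- unique(unlist(lapply(tree$rules, function(r) all.vars(r$expr))))
  miss <- setdiff(used, names(v))
  if (length(miss) > 0)
    stop("classifier vector is missing field(s): ",
         paste(miss, collapse = ", "))
  if (anyNA(v[, used, drop = FALSE]))
    stop("classifier vector contains missing values; ",
         "filter on computable vectors before assigning priority")
  n <- nrow(v)
  level <- rep(tree$default_level, n)
  assigned <- rep(FALSE, n)
  for (r in tree$rules) {
    hit <- eval(r$expr, envir = v, enclos = baseenv())
    hit <- rep_len(hit, n)
    take <- hit & !assigned
    level[take] <- r$level
    assigned <- assigned | take
  }
  maple_level_factor(level)
}

## Intact reference vector (documentation/example helper).
#' @rdname assign_priority
#' @export
classifier_vector_of_intact <- function() {
  data.frame(adl = 0L, cps = 0L, behavior = FALSE, decision_decline = FALSE,
             medication_problem = FALSE, pressure_ulcer = FALSE,
             fall = FALSE, meal_prep_problem = FALSE,
             swallowing_difficulty = FALSE, inst_risk_count = 0L,
             inst_risk_active = FALSE, screener = 0L)
}

#' Score a cohort: one priority level per computable time point
#'
#' @param cohort a [maple_cohort()].
#' @param tree a `maple_tree`.
#' @param ... options forwarded to [classifier_vector()].
#' @return data.frame `patient_id`, `timepoint`, `level` (ordered factor,
#'   NA where non-computable), `computable`, `blocking`; attribute
#'   `tree_version` records provenance.
#' @export
score_cohort <- function(cohort, tree = default_tree_spec(), ...) {
  out <- do.call(rbind, lapply(intersect(maple_timepoints(),
                                         unique(cohort$timepoint)),
                               function(tp) {
    v <- classifier_vector(cohort, tp, ...)
    level <- maple_level_factor(rep(NA_character_, nrow(v)))
    if (any(v$computable))
      level[v$computable] <- assign_priority(
        v[v$computable, , drop = FALSE], tree)
    data.frame(patient_id = v$patient_id, timepoint = tp, level = level,
               computable = v$computable, blocking = v$blocking)
  }))
  if (is.null(out))
    out <- data.frame(patient_id = character(), timepoint = character(),
                      level = maple_level_factor(character()),
                      computable = logical(), blocking = character())
  rownames(out) <- NULL
  attr(out, "tree_version") <- tree$version
  out
}

#' @rdname score_cohort
#' @param cohort_or_episode for `score_episode()`: a cohort holding (at
#'   least) the rows of one episode.
#' @param patient_id the episode to score.
#' @return `score_episode()`: named list with `levels` (named character,
#'   one per computable time point) and `non_computable` (named character
#'   of blocking classifiers per failed time point).
#' @export
score_episode <- function(cohort_or_episode, patient_id,
                          tree = default_tree_spec(), ...) {
  scored <- score_cohort(cohort_or_episode, tree, ...)
  scored <- scored[scored$patient_id == patient_id, , drop = FALSE]
  if (nrow(scored) == 0) stop("no rows for patient_id '", patient_id, "'")
  ok <- scored$computable
  absent <- setdiff(maple_timepoints(), scored$timepoint)
  list(levels = stats::setNames(as.character(scored$level[ok]),
                                scored$timepoint[ok]),
       non_computable = c(
         stats::setNames(scored$blocking[!ok], scored$timepoint[!ok]),
         stats::setNames(rep("assessment_missing", length(absent)), absent)),
       tree_version = attr(scored, "tree_version"))
}
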