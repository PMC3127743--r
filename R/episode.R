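## Episode container and CSV I/O.
##
## A cohort is held in one "long" data.frame: one row per
## (patient_id, timepoint), episode-level columns repeated on every row of
## the same patient, followed by the 31 crosswalk item columns. The missing
## sentinel is NA in memory and the empty field on disk.

cohort_column_order <- function() {
  c("patient_id", "timepoint", setdiff(episode_columns(), "patient_id"),
    item_codes())
}

#' Construct a cohort object from a long assessment table
#'
#' Validates column layout, value domains and episode-level consistency and
#' returns a `maple_cohort`, a thin S3 class over the long data.frame.
#'
#' @param df data.frame with one row per (patient_id, timepoint); columns
#'   as in [write_codebook()]'s codebook: identifiers, episode fields, then
#'   one column per crosswalk item.
#' @return A `maple_cohort` object.
#' @export
maple_cohort <- function(df) {
  miss <- setdiff(cohort_column_order(), names(df))
  if (length(miss) > 0)
    stop("cohort table is missing columns: ", paste(miss, collapse = ", "))
  df <- df[, cohort_column_order(), drop = FALSE]

  if (anyDuplicated(df[, c("patient_id", "timepoint")]))
    stop("duplicate (patient_id, timepoint) rows")
  bad_tp <- !df$timepoint %in% maple_timepoints()
  if (any(bad_tp))
    stop("unknown timepoint value(s): ",
         paste(unique(df$timepoint[bad_tp]), collapse = ", "))

  dom <- episode_enum_domains()
  for (cc in names(dom)) {
    v <- df[[cc]]
    bad <- !is.na(v) & !v %in% dom[[cc]]
    if (any(bad))
      stop("out-of-domain value in column '", cc, "': ",
           paste(unique(v[bad]), collapse = ", "))
  }
  for (cc in episode_logical_columns())
    df[[cc]] <- as.logical(df[[cc]])
  df$days_to_event <- as.integer(df$days_to_event)
  if (any(!is.na(df$days_to_event) &
            (df$days_to_event < 0 | df$days_to_event > 365)))
    stop("days_to_event must lie in 0..365")
  died_at_discharge <- !is.na(df$discharge_outcome) &
    df$discharge_outcome == "dead"
  if (any(died_at_discharge & !df$event_died %in% TRUE))
    stop("discharge_outcome 'dead' requires event_died = TRUE")

  ## episode-level columns must agree across a patient's rows
  ep_cols <- setdiff(episode_columns(), "patient_id")
  key <- paste0(df$patient_id)
  for (cc in ep_cols) {
    n_distinct <- tapply(df[[cc]], key, function(v)
      length(unique(v[!is.na(v)])))
    if (any(n_distinct > 1, na.rm = TRUE))
      stop("episode-level column '", cc,
           "' differs across time points for patient(s): ",
           paste(utils::head(names(n_distinct)[which(n_distinct > 1)], 5),
                 collapse = ", "))
  }

  im <- maple_item_map()
  for (i in seq_len(nrow(im))) {
    code <- im$item_code[i]
    vals <- item_domain_values(im$domain[i])
    v <- as.integer(df[[code]])
    bad <- !is.na(v) & !v %in% vals
    if (any(bad))
      stop("out-of-domain value for item '", code, "': ",
           paste(unique(v[bad]), collapse = ", "))
    df[[code]] <- v
  }

  rownames(df) <- NULL
  structure(df, class = c("maple_cohort", "data.frame"))
}

#' @export
print.maple_cohort <- function(x, ...) {
  n_ep <- length(unique(x$patient_id))
  cat("maple_cohort:", n_ep, "episodes,", nrow(x), "assessment rows\n")
  tab <- table(factor(x$timepoint, levels = maple_timepoints()))
  cat("  assessments per time point:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  rej <- attr(x, "rejections")
  if (!is.null(rej) && nrow(rej) > 0)
    cat("  rejected rows on read:", nrow(rej), "\n")
  invisible(x)
}

#' Read an episode CSV
#'
#' Reads the documented wide CSV dialect (header required, UTF-8, empty
#' field as missing sentinel). Rows with out-of-domain item values are
#' rejected, not fatal; each rejection is logged with the offending item
#' and row number in the `rejections` attribute. A malformed header or a
#' duplicate (patient_id, timepoint) pair is a hard error.
#'
#' @param path path to the CSV file.
#' @param codebook item map to validate against; defaults to the shipped
#'   31-item crosswalk map.
#' @return A [maple_cohort()], with attribute `rejections` (data.frame of
#'   row, item, value, reason).
#' @export
read_episodes <- function(path, codebook = maple_item_map()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character", na.strings = "",
                        check.names = FALSE)
  if (!identical(names(df), cohort_column_order()))
    stop("malformed header in ", path, ": expected columns ",
         paste(cohort_column_order(), collapse = ","))

  rejections <- data.frame(row = integer(), item = character(),
                           value = character(), reason = character())
  if (nrow(df) > 0) {
    keep <- rep(TRUE, nrow(df))
    for (i in seq_len(nrow(codebook))) {
      code <- codebook$item_code[i]
      vals <- item_domain_values(codebook$domain[i])
      v <- suppressWarnings(as.integer(df[[code]]))
      bad <- (!is.na(df[[code]]) & is.na(v)) | (!is.na(v) & !v %in% vals)
      if (any(bad)) {
        rejections <- rbind(rejections, data.frame(
          row = which(bad), item = code, value = df[[code]][bad],
          reason = sprintf("value out of domain {%s} for item '%s'",
                           paste(vals, collapse = ","), code)))
        keep[bad] <- FALSE
      }
    }
    df <- df[keep, , drop = FALSE]
  }
  for (code in codebook$item_code)
    df[[code]] <- suppressWarnings(as.integer(df[[code]]))
  df$days_to_event <- suppressWarnings(as.integer(df$days_to_event))
  for (cc in episode_logical_columns()) {
    v <- df[[cc]] %in% c("1", "TRUE")
    v[is.na(df[[cc]])] <- NA
    df[[cc]] <- v
  }

  out <- maple_cohort(df)
  attr(out, "rejections") <- rejections
  out
}

#' Write an episode CSV
#'
#' Inverse of [read_episodes()]: writes the documented CSV dialect with the
#' empty field as missing sentinel. `write_episodes()` then
#' `read_episodes()` round-trips value-identically.
#'
#' @param cohort a [maple_cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_episodes <- function(cohort, path) {
  df <- as.data.frame(cohort)
  for (cc in episode_logical_columns())
    df[[cc]] <- as.integer(df[[cc]])
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

## Items needed by each classifier, with the missing-data tier.
## "blocking": the classifier is non-computable without the item.
## "degraded": the item defaults to not-present with a warning.
classifier_requirements <- function() {
  im <- maple_item_map()
  consumers <- strsplit(im$consumers, ";", fixed = TRUE)
  long <- data.frame(
    classifier = unlist(consumers),
    item_code = rep(im$item_code, lengths(consumers)))
  long$tier <- ifelse(long$item_code %in% scale_critical_items(),
                      "blocking", "degraded")
  long
}

#' Report missing or unusable items for one assessment
#'
#' Applies the two-tier missing-data policy: items feeding the core scales
#' (ADL set, cognition set) block their classifier when absent; boolean
#' clinical/risk flags degrade gracefully to "not present". The report
#' groups problems by the classifier that needs the item.
#'
#' @param a one assessment: a one-row data.frame (or named list) holding
#'   item columns.
#' @param required character vector of classifier names to check (defaults
#'   to all classifiers the decision tree consumes).
#' @return data.frame with columns `classifier`, `item_code`, `tier`; zero
#'   rows iff every required classifier has all its items present.
#' @export
validate_assessment <- function(a,
                                required = unique(classifier_requirements()$classifier)) {
  a <- as.data.frame(as.list(a))
  req <- classifier_requirements()
  req <- req[req$classifier %in% required, , drop = FALSE]
  missing <- vapply(req$item_code, function(code) {
    !code %in% names(a) || is.na(a[[code]][1])
  }, logical(1))
  out <- req[missing, c("classifier", "item_code", "tier"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname validate_assessment
#' @param report a report returned by `validate_assessment()`.
#' @return `computable_classifiers()`: character vector of classifiers from
#'   `required` that have no blocking problems in `report`.
#' @export
computable_classifiers <- function(report,
                                   required = unique(classifier_requirements()$classifier)) {
  blocked <- unique(report$classifier[report$tier == "blocking"])
  setdiff(required, blocked)
}
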