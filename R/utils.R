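# Controlled vocabularies for report fields. Every demographic field carries an
# explicit "unknown" level so percentages are always over the full denominator.
SEX_LEVELS <- c("male", "female", "unknown")
AGE_LEVELS <- c("<18", "18-44", "45-64", "65-74", ">=75", "unknown")
REPORTER_LEVELS <- c("consumer", "physician", "other_hcp", "pharmacist", "lawyer", "unknown")
REGION_LEVELS <- c("americas", "europe", "asia", "oceania", "africa", "unknown")
SERIOUS_LEVELS <- c("yes", "no", "unknown")
SERIOUSNESS_CATEGORIES <- c("hospitalization", "life_threatening", "death",
                            "disabling", "congenital_anomaly", "other")
OUTCOME_LEVELS <- c("recovered", "recovering", "recovered_with_sequelae",
                    "not_recovered", "fatal", "unknown")
ACTION_LEVELS <- c("withdrawn", "dose_not_changed", "dose_reduced",
                   "dose_increased", "not_applicable", "unknown")
AFTER_ACTION_LEVELS <- c("abated", "no_effect", "unknown", "fatal")
ROLE_LEVELS <- c("suspect", "concomitant", "interacting")

#' Normalize a drug or preferred-term label
#'
#' Labels are matched case-insensitively after whitespace normalization:
#' leading/trailing whitespace is stripped, internal runs of whitespace are
#' collapsed to one space, and the result is lower-cased.
#'
#' @param x character vector of labels.
#' @return normalized character vector.
#' @export
norm_label <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Round half away from zero
#'
#' Display rounding for ratios (2 decimals) and percentages (1 decimal) uses
#' half-up rounding, not the IEEE banker's rounding of [round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  trunc(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) * sign(x) / p
}

# Split a pipe-delimited multi-value cell; "" means the empty set.
split_multi <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, "|", fixed = TRUE), function(v) v[nzchar(v)])
}

join_multi <- function(lst) {
  vapply(lst, paste, character(1), collapse = "|")
}

check_enum <- function(values, levels, field, rows = seq_along(values)) {
  bad <- !(values %in% levels)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("unknown %s value '%s' (row %d); allowed: %s",
                 field, values[i], rows[i], paste(levels, collapse = ", ")),
         call. = FALSE)
  }
  invisible(values)
}
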