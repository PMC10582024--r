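#' Construct an ICSR database
#'
#' An `icsr_db` holds a spontaneous-report database as three normalized tables
#' keyed by `report_id` plus a drug catalog. One report may carry several drugs
#' (each with a role code) and several preferred-term (PT) coded events; the
#' counting unit throughout the package is the report, not the patient.
#'
#' @param reports tibble with one row per report: `report_id`, `sex`,
#'   `age_band`, `reporter`, `region`, `year` (integer, `NA` = unknown),
#'   `serious`, `seriousness_categories` (pipe-delimited, empty unless
#'   `serious == "yes"`), `outcome`, `action_taken`, `outcome_after_action`,
#'   `indications` (pipe-delimited free-text condition labels, may be empty).
#' @param drugs tibble with one row per report-drug mention: `report_id`,
#'   `drug_name`, `role` (one of suspect, concomitant, interacting).
#' @param events tibble with one row per report-event mention: `report_id`,
#'   `pt_term`.
#' @param drug_catalog tibble `drug_name`, `is_mab` (logical flag marking
#'   membership in the monoclonal-antibody comparator class).
#' @param validate run invariant checks (default `TRUE`).
#'
#' @return an object of class `icsr_db`.
#' @export
icsr_db <- function(reports, drugs, events, drug_catalog, validate = TRUE) {
  reports <- tibble::as_tibble(reports)
  drugs <- tibble::as_tibble(drugs)
  events <- tibble::as_tibble(events)
  drug_catalog <- tibble::as_tibble(drug_catalog)

  drugs$drug_name <- norm_label(drugs$drug_name)
  events$pt_term <- norm_label(events$pt_term)
  drug_catalog$drug_name <- norm_label(drug_catalog$drug_name)
  drug_catalog$is_mab <- as.logical(drug_catalog$is_mab)

  db <- structure(list(reports = reports, drugs = drugs, events = events,
                       drug_catalog = drug_catalog),
                  class = "icsr_db")
  if (validate) validate_icsr_db(db)
  db
}

#' Validate an ICSR database against its invariants
#'
#' Checks report_id uniqueness, non-empty drug and event lists per report,
#' enumeration membership of every coded field, catalog coverage of every
#' referenced drug, and the seriousness rule (categories present iff
#' `serious == "yes"`). Violations raise an error with a row reference.
#'
#' @param db an `icsr_db`.
#' @return `db`, invisibly, if valid.
#' @export
validate_icsr_db <- function(db) {
  r <- db$reports
  required <- c("report_id", "sex", "age_band", "reporter", "region", "year",
                "serious", "seriousness_categories", "outcome", "action_taken",
                "outcome_after_action", "indications")
  missing_cols <- setdiff(required, names(r))
  if (length(missing_cols)) {
    stop("reports table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(r$report_id)) {
    dup <- r$report_id[duplicated(r$report_id)][1]
    stop(sprintf("duplicate report_id '%s'", dup), call. = FALSE)
  }
  check_enum(r$sex, SEX_LEVELS, "sex")
  check_enum(r$age_band, AGE_LEVELS, "age_band")
  check_enum(r$reporter, REPORTER_LEVELS, "reporter")
  check_enum(r$region, REGION_LEVELS, "region")
  check_enum(r$serious, SERIOUS_LEVELS, "serious")
  check_enum(r$outcome, OUTCOME_LEVELS, "outcome")
  check_enum(r$action_taken, ACTION_LEVELS, "action_taken")
  check_enum(r$outcome_after_action, AFTER_ACTION_LEVELS, "outcome_after_action")
  check_enum(db$drugs$role, ROLE_LEVELS, "role")

  cats <- split_multi(r$seriousness_categories)
  check_enum(unlist(cats), SERIOUSNESS_CATEGORIES, "seriousness_category")
  n_cats <- lengths(cats)
  bad <- (r$serious == "yes") != (n_cats > 0)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(paste0("report '%s' (row %d): seriousness_categories must be ",
                        "non-empty iff serious = yes"), r$report_id[i], i),
         call. = FALSE)
  }

  no_drug <- setdiff(r$report_id, db$drugs$report_id)
  if (length(no_drug)) {
    stop(sprintf("report '%s' lists no drugs", no_drug[1]), call. = FALSE)
  }
  no_event <- setdiff(r$report_id, db$events$report_id)
  if (length(no_event)) {
    stop(sprintf("report '%s' lists no events", no_event[1]), call. = FALSE)
  }
  orphan_drug <- setdiff(db$drugs$report_id, r$report_id)
  if (length(orphan_drug)) {
    stop(sprintf("report_drugs row references unknown report '%s'",
                 orphan_drug[1]), call. = FALSE)
  }
  orphan_event <- setdiff(db$events$report_id, r$report_id)
  if (length(orphan_event)) {
    stop(sprintf("report_events row references unknown report '%s'",
                 orphan_event[1]), call. = FALSE)
  }
  uncataloged <- setdiff(db$drugs$drug_name, db$drug_catalog$drug_name)
  if (length(uncataloged)) {
    stop(sprintf("drug '%s' is not in the drug catalog", uncataloged[1]),
         call. = FALSE)
  }
  invisible(db)
}

#' @export
print.icsr_db <- function(x, ...) {
  cat(sprintf("<icsr_db> %d reports, %d drug mentions, %d event mentions, %d catalog drugs (%d mAbs)\n",
              n_total(x), nrow(x$drugs), nrow(x$events),
              nrow(x$drug_catalog), sum(x$drug_catalog$is_mab)))
  invisible(x)
}

#' Number of reports in a database
#'
#' @param db an `icsr_db`.
#' @return integer count of reports.
#' @export
n_total <- function(db) nrow(db$reports)

report_csv_cols <- c("report_id", "sex", "age_band", "reporter", "region",
                     "year", "serious", "seriousness_categories", "outcome",
                     "action_taken", "outcome_after_action", "indications")

#' Read an ICSR database from a directory of CSV files
#'
#' Expects `reports.csv`, `report_drugs.csv`, `report_events.csv` and
#' `drug_catalog.csv` in the documented dialect (comma-separated, header row,
#' UTF-8, pipe-delimited multi-value cells, lowercase enumeration tokens,
#' `year` an integer or the token `unknown`). The database is validated on
#' read; invariant violations are fatal with a row reference.
#'
#' @param dir directory containing the four CSV files.
#' @return a validated `icsr_db`.
#' @export
read_icsr_db <- function(dir) {
  path <- function(f) file.path(dir, f)
  for (f in c("reports.csv", "report_drugs.csv", "report_events.csv",
              "drug_catalog.csv")) {
    if (!file.exists(path(f))) stop("missing database file: ", path(f), call. = FALSE)
  }
  read_chr <- function(f) {
    readr::read_csv(path(f), col_types = readr::cols(.default = readr::col_character()),
                    na = character(), progress = FALSE)
  }
  reports <- read_chr("reports.csv")
  missing_cols <- setdiff(report_csv_cols, names(reports))
  if (length(missing_cols)) {
    stop("reports.csv is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  yr <- reports$year
  bad_year <- !(yr == "unknown" | grepl("^[0-9]{4}$", yr))
  if (any(bad_year)) {
    stop(sprintf("reports.csv row %d: year '%s' is neither a 4-digit year nor 'unknown'",
                 which(bad_year)[1], yr[which(bad_year)[1]]), call. = FALSE)
  }
  reports$year <- suppressWarnings(as.integer(ifelse(yr == "unknown", NA, yr)))

  drugs <- read_chr("report_drugs.csv")
  events <- read_chr("report_events.csv")
  catalog <- read_chr("drug_catalog.csv")
  if (!all(c("drug_name", "is_mab") %in% names(catalog))) {
    stop("drug_catalog.csv must have columns drug_name, is_mab", call. = FALSE)
  }
  catalog$is_mab <- catalog$is_mab %in% c("TRUE", "true", "1", "yes")
  icsr_db(reports[report_csv_cols], drugs[c("report_id", "drug_name", "role")],
          events[c("report_id", "pt_term")], catalog[c("drug_name", "is_mab")])
}

#' Write an ICSR database to a directory of CSV files
#'
#' Emits the same four-file dialect that [read_icsr_db()] consumes; writing
#' then reading yields an equal database (round-trip property). Unknown years
#' are written as the token `unknown`.
#'
#' @param db a valid `icsr_db`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_icsr_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reports <- db$reports[report_csv_cols]
  reports$year <- ifelse(is.na(reports$year), "unknown", as.character(reports$year))
  paths <- c(reports = file.path(dir, "reports.csv"),
             drugs = file.path(dir, "report_drugs.csv"),
             events = file.path(dir, "report_events.csv"),
             catalog = file.path(dir, "drug_catalog.csv"))
  readr::write_csv(reports, paths["reports"], progress = FALSE)
  readr::write_csv(db$drugs, paths["drugs"], progress = FALSE)
  readr::write_csv(db$events, paths["events"], progress = FALSE)
  readr::write_csv(db$drug_catalog, paths["catalog"], progress = FALSE)
  invisible(paths)
}

#' Reports mentioning a drug in given roles
#'
#' Returns the IDs of reports in which `drug` appears with at least one of the
#' requested role codes. Deduplicated at report level: a report counts once
#' even if it lists the drug twice. The default role set
#' `{suspect, interacting}` is the one used for disproportionality; pass all
#' three roles for descriptive counts.
#'
#' @param db an `icsr_db`.
#' @param drug drug label (normalized before matching).
#' @param roles subset of `c("suspect", "concomitant", "interacting")`.
#' @return sorted character vector of unique report IDs.
#' @export
filter_by_role <- function(db, drug, roles = c("suspect", "interacting")) {
  drug <- norm_label(drug)
  if (!drug %in% db$drug_catalog$drug_name) {
    stop(sprintf("drug '%s' is not in the drug catalog", drug), call. = FALSE)
  }
  roles <- match.arg(roles, ROLE_LEVELS, several.ok = TRUE)
  hit <- db$drugs$drug_name == drug & db$drugs$role %in% roles
  sort(unique(db$drugs$report_id[hit]))
}
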