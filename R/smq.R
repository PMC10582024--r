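#' Construct an SMQ-style case definition
#'
#' A standardized MedDRA query (SMQ) here is a named set of preferred terms
#' (PTs) used as a case definition: a report is a case when at least one of
#' its events matches a term in the set. Only narrow-scope style exact term
#' sets are supported; no hierarchical MedDRA navigation or LLT-to-PT rollup
#' is performed — matching is exact label matching after case and whitespace
#' normalization.
#'
#' @param name query name.
#' @param pt_terms character vector of PT labels (deduplicated after
#'   normalization; must be non-empty).
#' @param scope `"narrow"` or `"broad"` (descriptive only).
#' @return an object of class `smq_definition`.
#' @export
smq_definition <- function(name, pt_terms, scope = "narrow") {
  pt_terms <- unique(norm_label(pt_terms))
  pt_terms <- pt_terms[nzchar(pt_terms)]
  if (!length(pt_terms)) stop("SMQ term list is empty", call. = FALSE)
  scope <- match.arg(scope, c("narrow", "broad"))
  structure(list(name = norm_label(name), scope = scope, pt_terms = pt_terms),
            class = "smq_definition")
}

#' @export
print.smq_definition <- function(x, ...) {
  cat(sprintf("<smq_definition> '%s' (%s scope), %d PTs\n",
              x$name, x$scope, length(x$pt_terms)))
  invisible(x)
}

#' Load an SMQ definition from a CSV file
#'
#' The file has columns `smq_name`, `scope`, `pt_term` (one row per term).
#' With no path, loads the bundled narrow-scope anaphylactic reaction query
#' (ten PTs: anaphylactic reaction, anaphylactic shock, anaphylactic
#' transfusion reaction, anaphylactoid reaction, circulatory collapse, Kounis
#' syndrome, procedural shock, shock, shock syndrome, type 1
#' hypersensitivity). The term set is shipped as data, not code, so licensed
#' MedDRA SMQs can be swapped in.
#'
#' @param path CSV file; `NULL` for the bundled default.
#' @return an `smq_definition`.
#' @export
load_smq <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "smq_anaphylactic_reaction.csv",
                        package = "pvsignal", mustWork = TRUE)
  }
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       na = character(), progress = FALSE)
  need <- c("smq_name", "scope", "pt_term")
  if (!all(need %in% names(x))) {
    stop("SMQ file must have columns smq_name, scope, pt_term", call. = FALSE)
  }
  if (!nrow(x)) stop("SMQ term list is empty", call. = FALSE)
  smq_definition(x$smq_name[1], x$pt_term, scope = x$scope[1])
}

#' Classify reports as cases under an SMQ definition
#'
#' Report-level classification: a report is one case no matter how many of
#' its events match the query. Insensitive to event ordering within a report.
#'
#' @param db an `icsr_db`.
#' @param smq an `smq_definition`.
#' @return tibble with one row per report: `report_id`, `is_case`,
#'   `matched_terms` (pipe-delimited matched PTs, empty for non-cases).
#' @export
classify_reports <- function(db, smq) {
  stopifnot(inherits(smq, "smq_definition"))
  ev <- db$events[db$events$pt_term %in% smq$pt_terms, ]
  matched <- tapply(ev$pt_term, ev$report_id,
                    function(v) paste(sort(unique(v)), collapse = "|"))
  out <- tibble::tibble(report_id = db$reports$report_id)
  out$matched_terms <- unname(matched[out$report_id])
  out$matched_terms[is.na(out$matched_terms)] <- ""
  out$is_case <- nzchar(out$matched_terms)
  out[c("report_id", "is_case", "matched_terms")]
}

#' Per-term case counts for one drug
#'
#' For each PT in the query, counts the role-filtered reports of `drug`
#' listing that PT, with the count as a percentage of the drug's role-filtered
#' report total (half-up, 1 decimal). Because one report may carry several
#' query terms, the per-term counts can sum to more than the report-level
#' case count.
#'
#' @param db an `icsr_db`.
#' @param smq an `smq_definition`.
#' @param drug drug label.
#' @param roles role subset, default all three roles (descriptive convention).
#' @return tibble `pt_term`, `n`, `denominator`, `percent`, one row per query
#'   term in query order.
#' @export
case_term_breakdown <- function(db, smq, drug,
                                roles = c("suspect", "concomitant", "interacting")) {
  ids <- filter_by_role(db, drug, roles)
  denom <- length(ids)
  ev <- db$events[db$events$report_id %in% ids &
                    db$events$pt_term %in% smq$pt_terms, ]
  counts <- vapply(smq$pt_terms, function(pt) {
    length(unique(ev$report_id[ev$pt_term == pt]))
  }, integer(1))
  tibble::tibble(
    pt_term = smq$pt_terms,
    n = unname(counts),
    denominator = denom,
    percent = if (denom > 0) round_half_up(100 * unname(counts) / denom, 1) else 0
  )
}
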