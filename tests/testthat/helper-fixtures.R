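# Fixtures are built in code, never stored on disk.

# Minimal valid report row; override fields as needed.
report_row <- function(report_id, ...) {
  defaults <- list(report_id = report_id, sex = "female", age_band = "18-44",
                   reporter = "physician", region = "americas", year = 2019L,
                   serious = "no", seriousness_categories = "",
                   outcome = "recovered", action_taken = "withdrawn",
                   outcome_after_action = "abated", indications = "asthma")
  over <- list(...)
  defaults[names(over)] <- over
  tibble::as_tibble(defaults)
}

# Assemble a database from per-report drug/event lists:
#   drugs:  list of data.frames (drug_name, role) per report
#   events: list of character PT vectors per report
make_db <- function(drugs, events, catalog, reports = NULL) {
  n <- length(drugs)
  ids <- sprintf("T%03d", seq_len(n))
  if (is.null(reports)) {
    reports <- dplyr::bind_rows(lapply(ids, report_row))
  }
  drug_tab <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    d <- tibble::as_tibble(drugs[[i]])
    d$report_id <- ids[i]
    d
  }))
  event_tab <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    tibble::tibble(report_id = ids[i], pt_term = events[[i]])
  }))
  icsr_db(reports, drug_tab[c("report_id", "drug_name", "role")],
          event_tab, catalog)
}

# The 4-report toy database: X+event, X alone, Y+event, Y alone.
toy_db <- function() {
  catalog <- tibble::tibble(drug_name = c("x", "y"), is_mab = c(TRUE, FALSE))
  make_db(
    drugs = list(
      data.frame(drug_name = "x", role = "suspect"),
      data.frame(drug_name = "x", role = "suspect"),
      data.frame(drug_name = "y", role = "suspect"),
      data.frame(drug_name = "y", role = "suspect")
    ),
    events = list(
      "anaphylactic reaction", "headache",
      "anaphylactic reaction", "headache"
    ),
    catalog = catalog
  )
}

# Independent brute-force oracle: per-report loop counting of the 2x2 cells,
# sharing no code with build_table().
brute_force_cells <- function(db, drug, pt_terms, comparator = "all_drugs",
                              roles = c("suspect", "interacting")) {
  a <- b <- cc <- d <- 0L
  for (rid in db$reports$report_id) {
    dr <- db$drugs[db$drugs$report_id == rid, ]
    has_drug <- any(dr$drug_name == drug & dr$role %in% roles)
    if (comparator == "all_mabs" && !has_drug) {
      mabs <- db$drug_catalog$drug_name[db$drug_catalog$is_mab]
      in_universe <- any(dr$drug_name %in% mabs & dr$role %in% roles)
      if (!in_universe) next
    }
    has_event <- any(db$events$pt_term[db$events$report_id == rid] %in% pt_terms)
    if (has_drug && has_event) a <- a + 1L
    else if (has_drug) b <- b + 1L
    else if (has_event) cc <- cc + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

# Scaled-down generator profile for quick tests.
small_profile <- function(n_reports = 2000, seed = 42) {
  default_biologics_profile(n_reports = n_reports, seed = seed)
}
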