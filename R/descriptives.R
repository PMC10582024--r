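count_block <- function(values, levels, block, denom, exclusive = TRUE) {
  counts <- vapply(levels, function(l) sum(values == l, na.rm = TRUE), integer(1))
  tibble::tibble(block = block, stratum = levels, count = unname(counts),
                 denominator = denom,
                 percent = if (denom > 0) round_half_up(100 * unname(counts) / denom, 1) else 0,
                 exclusive = exclusive)
}

#' Demographic breakdown of all reports and of case reports
#'
#' Produces the paired descriptive table of a safety screen: counts and
#' percentages by sex, age band, reporter type, continent of the primary
#' source, and year, plus single-row serious-case and death strata, a
#' condition (indication) block, and a per-drug block — once over every
#' report and once over case reports only. Percentages use the full
#' population denominator, with explicit "unknown" strata rather than
#' dropped records. The condition and drug blocks are non-exclusive (one
#' report may carry several), marked `exclusive = FALSE` and excluded from
#' the sum-to-denominator invariant. Deaths count reports with a fatal
#' outcome or a death seriousness category, deduplicated at report level.
#'
#' @param db an `icsr_db`.
#' @param case_flags classification tibble from [classify_reports()].
#' @return tibble with columns `population` (`"all"` / `"cases"`), `block`,
#'   `stratum`, `count`, `denominator`, `percent`, `exclusive`.
#' @export
demographics_table <- function(db, case_flags) {
  case_ids <- case_flags$report_id[case_flags$is_case]
  years <- sort(unique(db$reports$year[!is.na(db$reports$year)]))
  all_indic <- sort(unique(unlist(split_multi(db$reports$indications))))

  one_pop <- function(r, pop) {
    denom <- nrow(r)
    death <- r$outcome == "fatal" |
      vapply(split_multi(r$seriousness_categories),
             function(v) "death" %in% v, logical(1))
    year_lab <- ifelse(is.na(r$year), "unknown", as.character(r$year))
    indic <- split_multi(r$indications)
    indic_counts <- vapply(all_indic,
                           function(l) sum(vapply(indic, function(v) l %in% v, logical(1))),
                           integer(1))
    drug_tab <- db$drugs[db$drugs$report_id %in% r$report_id, ]
    drug_levels <- sort(unique(db$drug_catalog$drug_name))
    drug_counts <- vapply(drug_levels, function(dg) {
      length(unique(drug_tab$report_id[drug_tab$drug_name == dg]))
    }, integer(1))

    pc <- function(n) if (denom > 0) round_half_up(100 * n / denom, 1) else 0
    out <- dplyr::bind_rows(
      count_block(r$sex, SEX_LEVELS, "sex", denom),
      count_block(r$age_band, AGE_LEVELS, "age_band", denom),
      count_block(r$reporter, REPORTER_LEVELS, "reporter", denom),
      tibble::tibble(block = "serious", stratum = "serious",
                     count = sum(r$serious == "yes"), denominator = denom,
                     percent = pc(sum(r$serious == "yes")), exclusive = FALSE),
      tibble::tibble(block = "deaths", stratum = "deaths",
                     count = sum(death), denominator = denom,
                     percent = pc(sum(death)), exclusive = FALSE),
      count_block(r$region, REGION_LEVELS, "region", denom),
      count_block(year_lab, c(as.character(years), "unknown"), "year", denom),
      if (length(all_indic))
        tibble::tibble(block = "condition", stratum = all_indic,
                       count = unname(indic_counts), denominator = denom,
                       percent = pc(unname(indic_counts)), exclusive = FALSE),
      tibble::tibble(block = "condition", stratum = "unknown",
                     count = sum(lengths(indic) == 0), denominator = denom,
                     percent = pc(sum(lengths(indic) == 0)), exclusive = FALSE),
      tibble::tibble(block = "drug", stratum = drug_levels,
                     count = unname(drug_counts), denominator = denom,
                     percent = pc(unname(drug_counts)), exclusive = FALSE)
    )
    out$population <- pop
    out
  }

  res <- dplyr::bind_rows(
    one_pop(db$reports, "all"),
    one_pop(db$reports[db$reports$report_id %in% case_ids, ], "cases")
  )
  res[c("population", "block", "stratum", "count", "denominator", "percent",
        "exclusive")]
}

#' Per-drug seriousness, outcome, action and dechallenge tabulation
#'
#' Over each drug's serious case reports (case status from `case_flags`,
#' drug membership at any role — the descriptive convention), tabulates four
#' blocks: seriousness categories (multi-select, so a report can contribute
#' to several rows and the block may sum past its denominator), outcome,
#' action taken, and outcome after action (single-select blocks, which sum
#' exactly to the denominator). The per-drug denominator — the count of
#' serious case reports — is emitted alongside every row since percentages
#' are computed over it.
#'
#' @param db an `icsr_db`.
#' @param case_flags classification tibble from [classify_reports()].
#' @param drugs drug labels to tabulate.
#' @return tibble `drug`, `block`, `stratum`, `count`, `denominator`,
#'   `percent`, `exclusive`.
#' @export
seriousness_table <- function(db, case_flags, drugs) {
  drugs <- norm_label(drugs)
  case_ids <- case_flags$report_id[case_flags$is_case]
  out <- lapply(drugs, function(dg) {
    ids <- filter_by_role(db, dg, ROLE_LEVELS)
    r <- db$reports[db$reports$report_id %in% intersect(ids, case_ids) &
                      db$reports$serious == "yes", ]
    denom <- nrow(r)
    cats <- split_multi(r$seriousness_categories)
    cat_counts <- vapply(SERIOUSNESS_CATEGORIES,
                         function(l) sum(vapply(cats, function(v) l %in% v, logical(1))),
                         integer(1))
    blk <- dplyr::bind_rows(
      tibble::tibble(block = "seriousness_category",
                     stratum = SERIOUSNESS_CATEGORIES,
                     count = unname(cat_counts), denominator = denom,
                     percent = if (denom > 0) round_half_up(100 * unname(cat_counts) / denom, 1) else 0,
                     exclusive = FALSE),
      count_block(r$outcome, OUTCOME_LEVELS, "outcome", denom),
      count_block(r$action_taken, ACTION_LEVELS, "action_taken", denom),
      count_block(r$outcome_after_action, AFTER_ACTION_LEVELS,
                  "outcome_after_action", denom)
    )
    blk$drug <- dg
    blk
  })
  res <- dplyr::bind_rows(out)
  res[c("drug", "block", "stratum", "count", "denominator", "percent",
        "exclusive")]
}

#' Write descriptive tables to CSV
#'
#' @param demographics tibble from [demographics_table()].
#' @param seriousness tibble from [seriousness_table()].
#' @param dir output directory (created if absent).
#' @return invisibly, the two paths written.
#' @export
write_tables <- function(demographics, seriousness, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(demographics = file.path(dir, "demographics.csv"),
             seriousness = file.path(dir, "seriousness.csv"))
  readr::write_csv(demographics, paths["demographics"], progress = FALSE)
  readr::write_csv(seriousness, paths["seriousness"], progress = FALSE)
  invisible(paths)
}
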