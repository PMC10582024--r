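test_that("a small database validates and counts reports", {
  db <- toy_db()
  expect_s3_class(db, "icsr_db")
  expect_equal(n_total(db), 4)
})

test_that("validation rejects invariant violations with informative errors", {
  catalog <- tibble::tibble(drug_name = "x", is_mab = TRUE)
  # drug absent from catalog, named in the error
  expect_error(
    make_db(list(data.frame(drug_name = "mystery drug", role = "suspect")),
            list("headache"), catalog),
    "mystery drug"
  )
  # duplicate report ids
  reports <- dplyr::bind_rows(report_row("T001"), report_row("T001"))
  drugs <- tibble::tibble(report_id = c("T001", "T001"),
                          drug_name = "x", role = "suspect")
  events <- tibble::tibble(report_id = "T001", pt_term = "headache")
  expect_error(icsr_db(reports, drugs, events, catalog), "duplicate report_id")
  # unknown enumeration value, with field name
  expect_error(
    make_db(list(data.frame(drug_name = "x", role = "suspect")),
            list("headache"),
            catalog,
            reports = report_row("T001", sex = "none of the above")),
    "unknown sex value"
  )
  # seriousness categories must track the serious flag in both directions
  expect_error(
    make_db(list(data.frame(drug_name = "x", role = "suspect")),
            list("headache"), catalog,
            reports = report_row("T001", serious = "yes",
                                 seriousness_categories = "")),
    "seriousness_categories"
  )
  expect_error(
    make_db(list(data.frame(drug_name = "x", role = "suspect")),
            list("headache"), catalog,
            reports = report_row("T001", serious = "no",
                                 seriousness_categories = "death")),
    "seriousness_categories"
  )
  # reports must list at least one drug and one event
  expect_error(
    icsr_db(report_row("T001"), drugs[0, ], events, catalog),
    "no drugs"
  )
})

test_that("write then read round-trips a synthetic database exactly", {
  res <- generate_icsr(small_profile(n_reports = 1500, seed = 11))
  dir <- withr::local_tempdir()
  write_icsr_db(res$db, dir)
  back <- read_icsr_db(dir)
  expect_equal(back$reports, res$db$reports)
  expect_equal(back$drugs, res$db$drugs)
  expect_equal(back$events, res$db$events)
  expect_equal(back$drug_catalog, res$db$drug_catalog)
})

test_that("unknown years survive the round trip as NA", {
  catalog <- tibble::tibble(drug_name = "x", is_mab = TRUE)
  db <- make_db(list(data.frame(drug_name = "x", role = "suspect")),
                list("headache"), catalog,
                reports = report_row("T001", year = NA_integer_))
  dir <- withr::local_tempdir()
  write_icsr_db(db, dir)
  raw <- readr::read_csv(file.path(dir, "reports.csv"),
                         col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  expect_equal(raw$year, "unknown")
  expect_true(is.na(read_icsr_db(dir)$reports$year))
})

test_that("reading a file with a missing required column is fatal", {
  res <- generate_icsr(small_profile(n_reports = 50, seed = 3))
  dir <- withr::local_tempdir()
  write_icsr_db(res$db, dir)
  r <- readr::read_csv(file.path(dir, "reports.csv"),
                       col_types = readr::cols(.default = "c"),
                       na = character(), progress = FALSE)
  readr::write_csv(r[setdiff(names(r), "sex")], file.path(dir, "reports.csv"))
  expect_error(read_icsr_db(dir), "sex")
})

test_that("filter_by_role matches a hand count and deduplicates", {
  catalog <- tibble::tibble(drug_name = c("x", "y"), is_mab = c(TRUE, FALSE))
  db <- make_db(
    drugs = list(
      data.frame(drug_name = "x", role = "suspect"),
      # same drug twice in one report: must count once
      data.frame(drug_name = c("x", "x"), role = c("suspect", "interacting")),
      data.frame(drug_name = "x", role = "concomitant"),
      data.frame(drug_name = "y", role = "suspect"),
      data.frame(drug_name = "y", role = "concomitant")
    ),
    events = replicate(5, "headache", simplify = FALSE),
    catalog = catalog
  )
  si <- filter_by_role(db, "x", c("suspect", "interacting"))
  expect_length(si, 2)
  expect_false(anyDuplicated(si) > 0)
  # concomitant-only report excluded under the disproportionality roles
  expect_false("T003" %in% si)
  # monotone in the role set; all-roles count bounds each single-role count
  all_roles <- filter_by_role(db, "x", c("suspect", "concomitant", "interacting"))
  expect_true(all(si %in% all_roles))
  for (r in c("suspect", "concomitant", "interacting")) {
    expect_lte(length(filter_by_role(db, "x", r)), length(all_roles))
  }
  expect_error(filter_by_role(db, "nonexistent", "suspect"), "nonexistent")
})

test_that("labels are matched case-insensitively after whitespace normalization", {
  catalog <- tibble::tibble(drug_name = "Omalizumab", is_mab = TRUE)
  db <- make_db(list(data.frame(drug_name = "  OMALIZUMAB ", role = "suspect")),
                list("Anaphylactic  Reaction"), catalog)
  expect_length(filter_by_role(db, "omalizumab"), 1)
  expect_equal(db$events$pt_term, "anaphylactic reaction")
})
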