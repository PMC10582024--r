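#' Configuration for the synthetic ICSR generator
#'
#' Describes the generative model for a synthetic spontaneous-report
#' database: per report, a number of drug mentions is drawn from
#' `drugs_per_report`, drug names from the catalog selection probabilities,
#' and a role per mention from `role_distribution`; each preferred term is
#' then included with probability `background * m`, where `m` is the largest
#' planted relative reporting rate `rho` among the report's
#' suspect/interacting drugs for that term (`rho = 1` means no signal, and
#' concomitant mentions never transmit a signal — mirroring the analysis-side
#' role filter). Demographics are drawn independently from their marginals;
#' seriousness is drawn conditionally on case status (membership of any
#' `case_terms` event).
#'
#' @param n_reports number of reports to generate.
#' @param drug_catalog tibble `drug_name`, `prob`, `is_mab`; `prob` are the
#'   per-mention selection probabilities (normalized internally).
#' @param event_backgrounds named numeric: background per-report inclusion
#'   probability for each PT.
#' @param signal_matrix tibble `drug_name`, `pt_term`, `rho` of planted
#'   signals (`rho >= 0`, finite). `background * rho` must not exceed 1.
#' @param demographic_marginals list of named probability vectors for `sex`,
#'   `age_band`, `reporter`, `region`, `year` (names are year numbers) and
#'   `indication` (an `"unknown"` entry yields an empty indication list).
#' @param role_distribution named probabilities over suspect / concomitant /
#'   interacting.
#' @param drugs_per_report named probabilities over mention counts
#'   (names `"1"`, `"2"`, ...).
#' @param case_terms PT set defining case status for the seriousness model
#'   (defaults to the bundled anaphylaxis query terms).
#' @param p_serious named numeric `c(case = , noncase = )`: probability a
#'   report is serious given its case status.
#' @param seriousness_category_probs named distribution over seriousness
#'   categories for serious reports.
#' @param p_second_category probability a serious report carries a second,
#'   distinct seriousness category.
#' @param outcome_probs,action_probs,after_action_probs named distributions
#'   for the outcome, action-taken and outcome-after-action fields.
#' @param fallback_event PT assigned when a report draws no event at all, so
#'   the non-empty-events invariant always holds.
#' @param seed default seed used by [generate_icsr()] when none is passed.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_reports,
                             drug_catalog,
                             event_backgrounds,
                             signal_matrix = NULL,
                             demographic_marginals = default_demographic_marginals(),
                             role_distribution = c(suspect = 0.70, concomitant = 0.25,
                                                   interacting = 0.05),
                             drugs_per_report = c("1" = 0.65, "2" = 0.25,
                                                  "3" = 0.08, "4" = 0.02),
                             case_terms = load_smq()$pt_terms,
                             p_serious = c(case = 0.962, noncase = 0.347),
                             seriousness_category_probs = c(
                               hospitalization = 0.220, life_threatening = 0.129,
                               death = 0.006, disabling = 0.005,
                               congenital_anomaly = 0.001, other = 0.639),
                             p_second_category = 0.05,
                             outcome_probs = c(recovered = 0.354, recovering = 0.046,
                                               recovered_with_sequelae = 0.010,
                                               not_recovered = 0.017, fatal = 0.004,
                                               unknown = 0.569),
                             action_probs = c(withdrawn = 0.382, dose_not_changed = 0.053,
                                              dose_reduced = 0.008, dose_increased = 0.007,
                                              not_applicable = 0.012, unknown = 0.538),
                             after_action_probs = c(abated = 0.409, no_effect = 0.017,
                                                    unknown = 0.571, fatal = 0.003),
                             fallback_event = "drug ineffective",
                             seed = 1L) {
  drug_catalog <- tibble::as_tibble(drug_catalog)
  drug_catalog$drug_name <- norm_label(drug_catalog$drug_name)
  names(event_backgrounds) <- norm_label(names(event_backgrounds))
  if (is.null(signal_matrix) || !nrow(tibble::as_tibble(signal_matrix))) {
    signal_matrix <- tibble::tibble(drug_name = character(),
                                    pt_term = character(), rho = numeric())
  }
  signal_matrix <- tibble::as_tibble(signal_matrix)
  signal_matrix$drug_name <- norm_label(signal_matrix$drug_name)
  signal_matrix$pt_term <- norm_label(signal_matrix$pt_term)

  cfg <- structure(list(
    n_reports = as.integer(n_reports),
    drug_catalog = drug_catalog,
    event_backgrounds = event_backgrounds,
    signal_matrix = signal_matrix,
    demographic_marginals = demographic_marginals,
    role_distribution = role_distribution,
    drugs_per_report = drugs_per_report,
    case_terms = norm_label(case_terms),
    p_serious = p_serious,
    seriousness_category_probs = seriousness_category_probs,
    p_second_category = p_second_category,
    outcome_probs = outcome_probs,
    action_probs = action_probs,
    after_action_probs = after_action_probs,
    fallback_event = norm_label(fallback_event),
    seed = as.integer(seed)
  ), class = "generator_config")
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_reports >= 0)
  if (any(cfg$drug_catalog$prob < 0) || sum(cfg$drug_catalog$prob) <= 0) {
    stop("drug selection probabilities must be non-negative with positive sum",
         call. = FALSE)
  }
  if (any(cfg$event_backgrounds < 0 | cfg$event_backgrounds > 1)) {
    stop("event background probabilities must lie in [0, 1]", call. = FALSE)
  }
  sm <- cfg$signal_matrix
  if (nrow(sm)) {
    if (any(!is.finite(sm$rho)) || any(sm$rho < 0)) {
      stop("planted rho values must be finite and >= 0", call. = FALSE)
    }
    unknown_drug <- setdiff(sm$drug_name, cfg$drug_catalog$drug_name)
    if (length(unknown_drug)) {
      stop("signal_matrix names a drug absent from the catalog: ",
           unknown_drug[1], call. = FALSE)
    }
    unknown_pt <- setdiff(sm$pt_term, names(cfg$event_backgrounds))
    if (length(unknown_pt)) {
      stop("signal_matrix names a PT without a background rate: ",
           unknown_pt[1], call. = FALSE)
    }
    scaled <- cfg$event_backgrounds[sm$pt_term] * sm$rho
    if (any(scaled > 1)) {
      i <- which(scaled > 1)[1]
      stop(sprintf("probability overflow: background * rho = %.3g > 1 for pair (%s, %s)",
                   scaled[i], sm$drug_name[i], sm$pt_term[i]), call. = FALSE)
    }
  }
  for (f in names(cfg$demographic_marginals)) {
    p <- cfg$demographic_marginals[[f]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop(sprintf("demographic marginal '%s' must be a probability distribution", f),
           call. = FALSE)
    }
  }
  if (!cfg$fallback_event %in% names(cfg$event_backgrounds)) {
    stop("fallback_event must have a background rate", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> %d reports, %d catalog drugs (%d mAbs), %d PTs, %d planted signals, seed %d\n",
              x$n_reports, nrow(x$drug_catalog), sum(x$drug_catalog$is_mab),
              length(x$event_backgrounds), nrow(x$signal_matrix), x$seed))
  invisible(x)
}

# draw one categorical field of length n from a named probability vector
draw_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic ICSR database with ground truth
#'
#' Runs the generative model of [generator_config()] and returns both the
#' database and a ground-truth ledger: for every planted (drug, PT) pair, the
#' realized 2x2 cells under the analysis defaults (suspect/interacting role
#' filter, all-drugs comparator) counted by an independent set-arithmetic
#' pass over the raw draws, the planted `rho`, and the implied expected PRR.
#' Generation is vectorized from a single seeded stream, so a fixed seed
#' reproduces the database exactly.
#'
#' @param config a `generator_config`.
#' @param seed integer seed; defaults to the seed recorded in the config.
#' @return list with elements `db` (an `icsr_db`), `ground_truth` (tibble
#'   `drug_name`, `pt_term`, `rho`, `a`, `b`, `c`, `d`, `expected_prr`) and
#'   `n_cases` (realized report-level case count).
#' @export
generate_icsr <- function(config, seed = config$seed) {
  validate_generator_config(config)
  set.seed(seed)
  n <- config$n_reports
  ids <- sprintf("R%07d", seq_len(n))

  # drug mentions
  k <- as.integer(draw_cat(n, config$drugs_per_report))
  rid_idx <- rep.int(seq_len(n), k)
  mention_drug <- sample(config$drug_catalog$drug_name, length(rid_idx),
                         replace = TRUE, prob = config$drug_catalog$prob)
  mention_role <- draw_cat(length(rid_idx), config$role_distribution)
  si <- mention_role %in% c("suspect", "interacting")

  # events: per PT, background probability scaled by the strongest planted
  # rho among the report's suspect/interacting drugs
  sm <- config$signal_matrix
  event_idx <- vector("list", length(config$event_backgrounds))
  names(event_idx) <- names(config$event_backgrounds)
  for (pt in names(config$event_backgrounds)) {
    p <- rep(config$event_backgrounds[[pt]], n)
    rows <- which(sm$pt_term == pt)
    for (j in rows) {
      idx <- unique(rid_idx[si & mention_drug == sm$drug_name[j]])
      p[idx] <- pmax(p[idx], config$event_backgrounds[[pt]] * sm$rho[j])
    }
    event_idx[[pt]] <- which(runif(n) < p)
  }

  # every report must list at least one event
  with_event <- unique(unlist(event_idx, use.names = FALSE))
  empty <- setdiff(seq_len(n), with_event)
  if (length(empty)) {
    fb <- config$fallback_event
    event_idx[[fb]] <- sort(c(event_idx[[fb]], empty))
  }

  # demographics
  dm <- config$demographic_marginals
  sex <- draw_cat(n, dm$sex)
  age <- draw_cat(n, dm$age_band)
  reporter <- draw_cat(n, dm$reporter)
  region <- draw_cat(n, dm$region)
  year <- as.integer(draw_cat(n, dm$year))
  indication <- draw_cat(n, dm$indication)
  indication[indication == "unknown"] <- ""

  # case status and seriousness model
  case_terms <- intersect(config$case_terms, names(event_idx))
  case_idx <- unique(unlist(event_idx[case_terms], use.names = FALSE))
  is_case <- seq_len(n) %in% case_idx
  p_ser <- ifelse(is_case, config$p_serious[["case"]], config$p_serious[["noncase"]])
  serious <- ifelse(runif(n) < p_ser, "yes", "no")

  cat1 <- draw_cat(n, config$seriousness_category_probs)
  cat2 <- draw_cat(n, config$seriousness_category_probs)
  second <- runif(n) < config$p_second_category & cat2 != cat1
  cats <- ifelse(serious == "yes",
                 ifelse(second, paste(cat1, cat2, sep = "|"), cat1), "")

  reports <- tibble::tibble(
    report_id = ids, sex = sex, age_band = age, reporter = reporter,
    region = region, year = year, serious = serious,
    seriousness_categories = cats,
    outcome = draw_cat(n, config$outcome_probs),
    action_taken = draw_cat(n, config$action_probs),
    outcome_after_action = draw_cat(n, config$after_action_probs),
    indications = indication
  )
  drugs <- tibble::tibble(report_id = ids[rid_idx], drug_name = mention_drug,
                          role = mention_role)
  events <- tibble::tibble(
    report_id = ids[unlist(event_idx, use.names = FALSE)],
    pt_term = rep(names(event_idx), lengths(event_idx))
  )
  events <- events[order(events$report_id, events$pt_term), ]
  db <- icsr_db(reports, drugs, events,
                config$drug_catalog[c("drug_name", "is_mab")])

  # ground truth: independent recount of the realized cells from raw draws
  gt <- sm
  if (nrow(gt)) {
    cells <- lapply(seq_len(nrow(gt)), function(j) {
      si_reports <- unique(rid_idx[si & mention_drug == gt$drug_name[j]])
      ev_reports <- event_idx[[gt$pt_term[j]]]
      a <- length(intersect(si_reports, ev_reports))
      b <- length(si_reports) - a
      cc <- length(ev_reports) - a
      d <- n - length(si_reports) - cc
      c(a = a, b = b, c = cc, d = d)
    })
    cells <- do.call(rbind, cells)
    gt$a <- cells[, "a"]; gt$b <- cells[, "b"]
    gt$c <- cells[, "c"]; gt$d <- cells[, "d"]
    gt$expected_prr <- gt$rho
  } else {
    gt$a <- gt$b <- gt$c <- gt$d <- integer()
    gt$expected_prr <- numeric()
  }

  list(db = db, ground_truth = gt, n_cases = sum(is_case))
}

#' Demographic marginals emulating a large real-world biologic safety screen
#'
#' Categorical distributions for sex, age band, reporter type, continent,
#' reporting year and indication matching the all-report margins of a global
#' spontaneous-report screen of asthma biologics (female-predominant,
#' consumer-reported, Americas-weighted). Years at or before 2015 are pooled
#' on 2015.
#'
#' @return named list of named probability vectors.
#' @export
default_demographic_marginals <- function() {
  norm1 <- function(p) p / sum(p)
  list(
    sex = norm1(c(male = 0.312, female = 0.609, unknown = 0.079)),
    age_band = norm1(c("<18" = 0.040, "18-44" = 0.190, "45-64" = 0.231,
                       "65-74" = 0.067, ">=75" = 0.031, unknown = 0.441)),
    reporter = norm1(c(consumer = 0.464, physician = 0.319, other_hcp = 0.154,
                       pharmacist = 0.038, lawyer = 0.0002, unknown = 0.025)),
    region = norm1(c(americas = 0.808, europe = 0.154, asia = 0.027,
                     oceania = 0.009, africa = 0.002, unknown = 0)),
    year = norm1(c("2015" = 0.159, "2016" = 0.071, "2017" = 0.145,
                   "2018" = 0.204, "2019" = 0.420)),
    indication = norm1(c(asthma = 0.331, urticaria = 0.095, dermatitis = 0.165,
                         "other condition" = 0.059, unknown = 0.350))
  )
}

#' Default generator profile: five asthma biologics in a mixed drug universe
#'
#' A ready-to-run [generator_config()] emulating the structure of the
#' database behind a biologic anaphylaxis screen: the five asthma biologics
#' (omalizumab, mepolizumab, benralizumab, reslizumab, dupilumab) flagged as
#' mAbs, a configurable count of background drugs (the first five of which
#' are also flagged as mAbs so the restricted comparator has a universe),
#' anaphylaxis-query PTs at realistic background rates, common background
#' PTs, demographic marginals from [default_demographic_marginals()], and
#' planted anaphylactic-reaction signals whose relative reporting rates echo
#' the screen's reported effect sizes (omalizumab ~9.6, benralizumab ~4.9,
#' mepolizumab ~2.5, dupilumab ~0.4, plus an omalizumab type 1
#' hypersensitivity signal ~6.1). Biologics jointly receive about 30% of
#' drug mentions — far above their share of a real global database — so that
#' moderate simulation sizes yield workable per-drug counts.
#'
#' @param n_reports number of reports (default 20000).
#' @param n_background_drugs count of non-biologic catalog drugs (default 20,
#'   minimum 5).
#' @param plant_signals `FALSE` yields the null profile (`rho == 1`
#'   everywhere), the reference condition for false-positive-rate checks.
#' @param seed seed recorded in the config.
#' @return a `generator_config`.
#' @export
default_biologics_profile <- function(n_reports = 20000, n_background_drugs = 20,
                                  plant_signals = TRUE, seed = 1L) {
  stopifnot(n_background_drugs >= 5)
  biologics <- c("omalizumab", "mepolizumab", "benralizumab", "reslizumab",
                 "dupilumab")
  # biologic shares proportional to their report totals in the emulated screen
  bio_share <- c(32618, 7344, 2387, 315, 20559)
  bio_prob <- 0.30 * bio_share / sum(bio_share)
  bg_names <- sprintf("backgrounddrug%02d", seq_len(n_background_drugs))
  catalog <- tibble::tibble(
    drug_name = c(biologics, bg_names),
    prob = c(bio_prob, rep(0.70 / n_background_drugs, n_background_drugs)),
    is_mab = c(rep(TRUE, 5),
               seq_len(n_background_drugs) <= 5)
  )
  backgrounds <- c(
    "anaphylactic reaction" = 4.6e-3,
    "anaphylactic shock" = 1.5e-3,
    "anaphylactic transfusion reaction" = 5e-5,
    "anaphylactoid reaction" = 9e-4,
    "circulatory collapse" = 4e-4,
    "kounis syndrome" = 5e-5,
    "procedural shock" = 5e-5,
    "shock" = 9e-4,
    "shock syndrome" = 5e-5,
    "type 1 hypersensitivity" = 2e-4,
    # common background PTs
    "drug ineffective" = 0.08, "headache" = 0.06, "injection site reaction" = 0.05,
    "nausea" = 0.05, "dyspnoea" = 0.04, "rash" = 0.04, "fatigue" = 0.03,
    "dizziness" = 0.03, "pyrexia" = 0.03, "urticaria" = 0.02, "cough" = 0.02,
    "arthralgia" = 0.02
  )
  signals <- if (plant_signals) {
    tibble::tibble(
      drug_name = c("omalizumab", "omalizumab", "benralizumab", "mepolizumab",
                    "dupilumab"),
      pt_term = c("anaphylactic reaction", "type 1 hypersensitivity",
                  "anaphylactic reaction", "anaphylactic reaction",
                  "anaphylactic reaction"),
      rho = c(9.6, 6.1, 4.9, 2.5, 0.4)
    )
  } else NULL
  generator_config(n_reports = n_reports, drug_catalog = catalog,
                   event_backgrounds = backgrounds, signal_matrix = signals,
                   seed = seed)
}

#' Parameter-recovery profile: isolated planted signals on separate PTs
#'
#' A validation scenario for estimator calibration: each planted relative
#' reporting rate sits on its own drug and its own PT, so no signal
#' contaminates another's comparator cells and the screened PRR estimates
#' the planted `rho` directly in the rare-event regime. Drug selection
#' probabilities (0.12 per planted drug) and the 2e-3 PT backgrounds are
#' sized so the expected event count per planted pair exceeds 50 at
#' `rho = 2` for 200,000 reports.
#'
#' @param n_reports number of reports (default 200000).
#' @param rhos planted relative reporting rates, one drug-PT pair each
#'   (default `c(2, 5, 10)`).
#' @param seed seed recorded in the config.
#' @return a `generator_config`; planted drugs are named `signaldrug1`,
#'   `signaldrug2`, ... and their PTs `signal pt 1`, `signal pt 2`, ...
#' @export
planted_recovery_profile <- function(n_reports = 200000, rhos = c(2, 5, 10),
                                     seed = 1L) {
  k <- length(rhos)
  planted <- sprintf("signaldrug%d", seq_len(k))
  pts <- sprintf("signal pt %d", seq_len(k))
  n_filler <- 7
  fillers <- sprintf("fillerdrug%d", seq_len(n_filler))
  catalog <- tibble::tibble(
    drug_name = c(planted, fillers),
    prob = c(rep(0.12, k), rep((1 - 0.12 * k) / n_filler, n_filler)),
    is_mab = c(rep(TRUE, k), seq_len(n_filler) <= 2)
  )
  backgrounds <- c(setNames(rep(2e-3, k), pts),
                   "drug ineffective" = 0.10, "headache" = 0.08,
                   "nausea" = 0.05)
  generator_config(
    n_reports = n_reports, drug_catalog = catalog,
    event_backgrounds = backgrounds,
    signal_matrix = tibble::tibble(drug_name = planted, pt_term = pts,
                                   rho = rhos),
    case_terms = pts,
    seed = seed
  )
}
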