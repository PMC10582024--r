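#' Construct a 2x2 contingency table for a drug-event pair
#'
#' Cell layout (report counts, deduplicated at report level):
#' \tabular{lcc}{
#'               \tab event of interest \tab all other events \cr
#'   drug of interest \tab a \tab b \cr
#'   all other drugs in comparator \tab c \tab d
#' }
#' so `a + b` is the drug's role-filtered report total and `a + b + c + d`
#' is the comparator universe size.
#'
#' @param a,b,c,d non-negative report counts.
#' @param drug,event_label,comparator,roles provenance fields (optional).
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, drug = NA_character_,
                              event_label = NA_character_,
                              comparator = NA_character_, roles = character()) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("contingency cells must be non-negative counts", call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, d = d, drug = drug,
                 event_label = event_label, comparator = comparator,
                 roles = roles),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %s / %s vs %s (roles: %s)\n",
              x$drug, x$event_label, x$comparator,
              paste(x$roles, collapse = ",")))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("drug", "comparator"), c("event", "other")))
  print(m)
  invisible(x)
}

#' Build the 2x2 table for a drug-event pair from a database
#'
#' The drug's reports are those where it appears with a role in `roles`
#' (default suspect or interacting, the disproportionality convention). The
#' comparator universe is every report in the database (`all_drugs`) or every
#' report carrying at least one catalog-flagged monoclonal antibody with a
#' role in `roles` (`all_mabs`); the drug's own reports are excluded from the
#' comparator cells, so `a + b + c + d` equals the universe size. All cells
#' count reports once each, never event mentions.
#'
#' @param db an `icsr_db`.
#' @param drug drug label (must be in the catalog; for `all_mabs` it must be
#'   flagged as a mAb).
#' @param event a PT label, or an `smq_definition` to use the whole query as
#'   the event of interest.
#' @param comparator `"all_drugs"` or `"all_mabs"`.
#' @param roles role subset defining the drug's reports.
#' @return a `contingency_table`.
#' @export
build_table <- function(db, drug, event, comparator = c("all_drugs", "all_mabs"),
                        roles = c("suspect", "interacting")) {
  comparator <- match.arg(comparator)
  drug <- norm_label(drug)
  drug_ids <- filter_by_role(db, drug, roles)

  if (inherits(event, "smq_definition")) {
    terms <- event$pt_terms
    event_label <- paste0(event$name, " (smq)")
  } else {
    terms <- norm_label(event)
    event_label <- terms
  }
  event_ids <- unique(db$events$report_id[db$events$pt_term %in% terms])

  if (comparator == "all_mabs") {
    mabs <- db$drug_catalog$drug_name[db$drug_catalog$is_mab]
    if (!drug %in% mabs) {
      stop(sprintf("drug '%s' is not flagged as a mAb; cannot use the all_mabs comparator",
                   drug), call. = FALSE)
    }
    hit <- db$drugs$drug_name %in% mabs & db$drugs$role %in% roles
    universe <- unique(db$drugs$report_id[hit])
  } else {
    universe <- db$reports$report_id
  }
  if (!length(universe)) stop("comparator universe is empty", call. = FALSE)

  a <- sum(drug_ids %in% event_ids)
  b <- length(drug_ids) - a
  comp <- setdiff(universe, drug_ids)
  cc <- sum(comp %in% event_ids)
  d <- length(comp) - cc
  contingency_table(a, b, cc, d, drug = drug, event_label = event_label,
                    comparator = comparator, roles = roles)
}

cells_of <- function(x, b, c, d) {
  if (inherits(x, "contingency_table")) list(a = x$a, b = x$b, c = x$c, d = x$d)
  else list(a = x, b = b, c = c, d = d)
}

#' Proportional reporting ratio
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`: the event's reporting proportion among the
#' drug's reports over the same proportion in the comparator. Evaluated
#' exactly per formula with no continuity correction; when the comparator
#' proportion is undefined (`c = 0` or empty margins) the result is `NA`
#' rather than an error, so screens can carry undefined metrics through.
#'
#' @param x a `contingency_table`, or the cell `a` with `b`, `c`, `d` given
#'   (vectorized in the latter form).
#' @param b,c,d remaining cells when `x` is numeric.
#' @return numeric PRR (`NA` when undefined; 0 when `a = 0`).
#' @export
prr <- function(x, b = NULL, c = NULL, d = NULL) {
  k <- cells_of(x, b, c, d)
  out <- (k$a / (k$a + k$b)) / (k$c / (k$c + k$d))
  out[k$a + k$b == 0 | k$c + k$d == 0 | k$c == 0] <- NA_real_
  out
}

#' Reporting odds ratio
#'
#' `ROR = (a/b) / (c/d)`, the odds-ratio form of the same comparison as
#' [prr()]. Undefined (`NA`) when any of `b`, `c`, `d` is zero; see
#' [ror_corrected()] for a Haldane-corrected companion value in that case.
#'
#' @inheritParams prr
#' @return numeric ROR (`NA` when undefined).
#' @export
ror <- function(x, b = NULL, c = NULL, d = NULL) {
  k <- cells_of(x, b, c, d)
  out <- (k$a / k$b) / (k$c / k$d)
  out[k$b == 0 | k$c == 0 | k$d == 0] <- NA_real_
  out
}

#' Haldane-corrected reporting odds ratio
#'
#' Adds 0.5 to every cell before forming the odds ratio. Reported alongside —
#' never silently in place of — the uncorrected [ror()], whose formula has no
#' correction; use it only where a zero cell makes the plain ROR undefined.
#'
#' @inheritParams prr
#' @return numeric corrected ROR (always finite).
#' @export
ror_corrected <- function(x, b = NULL, c = NULL, d = NULL) {
  k <- cells_of(x, b, c, d)
  ((k$a + 0.5) / (k$b + 0.5)) / ((k$c + 0.5) / (k$d + 0.5))
}

#' Information component with 95% credibility lower bound
#'
#' The information component is the log2 observed-to-expected reporting ratio
#' under independence, `IC = log2 P(drug, event) / (P(drug) P(event))`,
#' estimated with the shrinkage observed/expected form used operationally
#' with large spontaneous-report databases: with observed `O = a` and
#' expected `E = (a+b)(a+c)/(a+b+c+d)`,
#' \deqn{IC = \log_2 \frac{O + 0.5}{E + 0.5}.}
#' The lower 2.5% credibility bound `IC025` uses, by default, the published
#' closed-form approximation
#' \deqn{IC_{025} = IC - 3.3 (O + 0.5)^{-1/2} - 2.363 (O + 0.5)^{-3/4},}
#' or, with `method = "gamma_quantile"`, the exact posterior quantile
#' `log2 qgamma(0.025; O + 0.5, E + 0.5)` (shape/rate). Shrinkage makes every
#' cell admissible: `a = E = 0` gives `IC = 0` exactly, and `IC025 < IC`
#' always.
#'
#' @inheritParams prr
#' @param method `"approx"` (closed-form credibility bound, default) or
#'   `"gamma_quantile"` (exact posterior quantile).
#' @return list with numeric components `ic` and `ic025` (bits).
#' @export
ic <- function(x, b = NULL, c = NULL, d = NULL,
               method = c("approx", "gamma_quantile")) {
  method <- match.arg(method)
  k <- cells_of(x, b, c, d)
  n <- k$a + k$b + k$c + k$d
  e <- ifelse(n > 0, (k$a + k$b) * (k$a + k$c) / n, 0)
  o <- k$a
  ic_val <- log2((o + 0.5) / (e + 0.5))
  ic025 <- if (method == "approx") {
    ic_val - 3.3 * (o + 0.5)^(-1 / 2) - 2.363 * (o + 0.5)^(-3 / 4)
  } else {
    log2(qgamma(0.025, shape = o + 0.5, rate = e + 0.5))
  }
  list(ic = ic_val, ic025 = ic025)
}

#' Signal detection criteria
#'
#' The default rule flags a drug-event pair reported at least three times
#' whose PRR and ROR are both at least 2 and whose IC025 is at least 0
#' (conjunctive across all four conditions).
#'
#' @param min_reports minimum report count `a` (default 3).
#' @param prr_threshold PRR threshold (default 2).
#' @param ror_threshold ROR threshold (default 2).
#' @param ic025_threshold IC025 threshold in bits (default 0).
#' @return an object of class `signal_criteria`.
#' @export
signal_criteria <- function(min_reports = 3, prr_threshold = 2,
                            ror_threshold = 2, ic025_threshold = 0) {
  stopifnot(min_reports >= 1, is.finite(prr_threshold), is.finite(ror_threshold),
            is.finite(ic025_threshold))
  structure(list(min_reports = min_reports, prr_threshold = prr_threshold,
                 ror_threshold = ror_threshold, ic025_threshold = ic025_threshold),
            class = "signal_criteria")
}

#' Classify a drug-event pair as a positive signal
#'
#' Conjunctive rule: positive iff `n >= min_reports` AND
#' `prr >= prr_threshold` AND `ror >= ror_threshold` AND
#' `ic025 >= ic025_threshold`. An undefined (`NA`) metric never yields a
#' positive signal. Vectorized over its metric arguments.
#'
#' @param n report count (cell `a`).
#' @param prr,ror,ic025 the disproportionality metrics.
#' @param criteria a [signal_criteria()] object.
#' @return logical vector.
#' @export
classify_signal <- function(n, prr, ror, ic025, criteria = signal_criteria()) {
  pos <- n >= criteria$min_reports &
    !is.na(prr) & prr >= criteria$prr_threshold &
    !is.na(ror) & ror >= criteria$ror_threshold &
    !is.na(ic025) & ic025 >= criteria$ic025_threshold
  pos & !is.na(pos)
}

#' Back-solve the ROR from a printed (count, drug total, PRR) triple
#'
#' Internal-consistency check over published screening tables: given the
#' event count `a`, the drug's report total `n_drug`, and the printed PRR,
#' recovers the comparator proportion `p = (a/n_drug)/prr`, forms the
#' comparator odds `p/(1-p)` and the drug odds `a/(n_drug - a)`, and returns
#' their ratio — the ROR implied by the PRR without access to the underlying
#' database. Vectorized.
#'
#' @param a event report count for the drug.
#' @param n_drug the drug's total report count (`a + b`).
#' @param prr the printed PRR (> 0).
#' @return numeric implied ROR.
#' @export
ror_from_prr <- function(a, n_drug, prr) {
  stopifnot(all(a > 0), all(a < n_drug), all(prr > 0))
  p <- (a / n_drug) / prr
  if (any(p >= 1)) {
    stop("inconsistent inputs: implied comparator proportion >= 1", call. = FALSE)
  }
  (a / (n_drug - a)) / (p / (1 - p))
}

#' Screen a drug list against an SMQ case definition
#'
#' For each drug, computes one disproportionality result per query PT with at
#' least one report (`a >= 1`) plus one aggregate result for the query as a
#' whole (labelled `"<smq name> (smq)"`). Rows are ordered by drug (in the
#' order given), then descending `a`, then event label — a deterministic
#' ordering suitable for byte-stable output.
#'
#' @param db an `icsr_db`.
#' @param drugs character vector of drug labels to screen.
#' @param smq an `smq_definition`.
#' @param criteria a [signal_criteria()].
#' @param comparator `"all_drugs"` or `"all_mabs"`.
#' @param roles role subset for the drug cells (default suspect/interacting).
#' @param ic_method credibility-bound method passed to [ic()].
#' @return tibble with columns `drug`, `event_label`, `comparator`, `a`, `b`,
#'   `c`, `d`, `prr`, `ror`, `ic`, `ic025`, `signal_positive`.
#' @export
screen_signals <- function(db, drugs, smq, criteria = signal_criteria(),
                           comparator = c("all_drugs", "all_mabs"),
                           roles = c("suspect", "interacting"),
                           ic_method = c("approx", "gamma_quantile")) {
  comparator <- match.arg(comparator)
  ic_method <- match.arg(ic_method)
  drugs <- norm_label(drugs)

  event_sets <- lapply(smq$pt_terms, function(pt) {
    unique(db$events$report_id[db$events$pt_term == pt])
  })
  names(event_sets) <- smq$pt_terms
  smq_set <- unique(unlist(event_sets, use.names = FALSE))

  if (comparator == "all_mabs") {
    mabs <- db$drug_catalog$drug_name[db$drug_catalog$is_mab]
    hit <- db$drugs$drug_name %in% mabs & db$drugs$role %in% roles
    universe <- unique(db$drugs$report_id[hit])
  } else {
    universe <- db$reports$report_id
  }
  if (!length(universe)) stop("comparator universe is empty", call. = FALSE)

  rows <- lapply(drugs, function(dg) {
    drug_ids <- filter_by_role(db, dg, roles)
    comp <- setdiff(universe, drug_ids)
    n_drug <- length(drug_ids)
    n_comp <- length(comp)
    one <- function(ids, label) {
      a <- sum(drug_ids %in% ids)
      cc <- sum(comp %in% ids)
      tibble::tibble(drug = dg, event_label = label, comparator = comparator,
                     a = a, b = n_drug - a, c = cc, d = n_comp - cc)
    }
    per_pt <- lapply(names(event_sets), function(pt) one(event_sets[[pt]], pt))
    per_pt <- dplyr::bind_rows(per_pt)
    per_pt <- per_pt[per_pt$a >= 1, ]
    agg <- one(smq_set, paste0(smq$name, " (smq)"))
    block <- dplyr::bind_rows(agg, per_pt)
    block[order(-block$a, block$event_label), ]
  })
  out <- dplyr::bind_rows(rows)
  out$prr <- prr(out$a, out$b, out$c, out$d)
  out$ror <- ror(out$a, out$b, out$c, out$d)
  ics <- ic(out$a, out$b, out$c, out$d, method = ic_method)
  out$ic <- ics$ic
  out$ic025 <- ics$ic025
  out$signal_positive <- classify_signal(out$a, out$prr, out$ror, out$ic025,
                                         criteria)
  out
}

#' Write screen results to CSV
#'
#' Ratios and IC values are written at full precision; row order is the
#' deterministic order produced by [screen_signals()].
#'
#' @param results tibble from [screen_signals()] (possibly several stacked
#'   comparator tracks).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_signals <- function(results, path) {
  readr::write_csv(results, path, progress = FALSE)
  invisible(path)
}
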