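# Cells for the headline drug-event pair, back-solved from the reference
# screen's printed PRR (9.61), drug total (32,457) and database size
# (21,161,249); frozen expected values computed by direct evaluation of the
# closed-form formulas.
HEADLINE <- list(a = 1437, b = 31020, c = 97341, d = 21031451)

test_that("build_table enumerates the toy database correctly", {
  db <- toy_db()
  t <- build_table(db, "x", "anaphylactic reaction", "all_drugs")
  expect_equal(c(t$a, t$b, t$c, t$d), c(1, 1, 1, 1))
  expect_equal(t$a + t$b + t$c + t$d, n_total(db))
  expect_equal(prr(t), 1)
  expect_equal(ror(t), 1)
})

test_that("a degenerate mAb comparator yields zero comparator cells and NA metrics", {
  db <- toy_db()  # only x is a mAb
  t <- build_table(db, "x", "anaphylactic reaction", "all_mabs")
  expect_equal(c(t$c, t$d), c(0, 0))
  expect_true(is.na(prr(t)))
  expect_true(is.na(ror(t)))
  expect_false(classify_signal(t$a, prr(t), ror(t), ic(t)$ic025))
})

test_that("PRR matches its formula on hand-checked cells", {
  expect_equal(prr(1, 1, 1, 1), 1)
  expect_equal(prr(0, 5, 3, 7), 0)
  h <- HEADLINE
  expect_equal(prr(h$a, h$b, h$c, h$d), 9.610086, tolerance = 1e-6)
  expect_equal(round_half_up(prr(h$a, h$b, h$c, h$d), 2), 9.61)
  expect_true(is.na(prr(3, 1, 0, 10)))      # c = 0 undefined, not fatal
  expect_true(is.na(prr(0, 0, 3, 10)))      # empty drug margin
})

test_that("ROR matches its formula and flags zero cells as undefined", {
  expect_equal(ror(2, 4, 3, 6), 1)          # a*d = b*c -> null association
  h <- HEADLINE
  expect_equal(ror(h$a, h$b, h$c, h$d), 10.00895, tolerance = 1e-6)
  expect_equal(round_half_up(ror(h$a, h$b, h$c, h$d), 2), 10.01)
  expect_true(is.na(ror(3, 0, 1, 10)))
  expect_true(is.na(ror(3, 1, 0, 10)))
  expect_true(is.na(ror(3, 1, 2, 0)))
  # the Haldane companion value is finite exactly where ror is undefined
  expect_true(is.finite(ror_corrected(3, 0, 1, 10)))
  expect_equal(ror_corrected(3, 0, 1, 10),
               (3.5 / 0.5) / (1.5 / 10.5))
})

test_that("IC shrinkage estimator and credibility bound behave as specified", {
  # independence at large counts: IC ~ 0, IC025 < 0
  big <- ic(1000, 99000, 9000, 891000)   # E = a exactly under independence
  expect_equal(big$ic, 0, tolerance = 1e-3)
  expect_lt(big$ic025, 0)
  # shrinkage fixed point: a = 0, E = 0 -> IC = log2(0.5/0.5) = 0
  expect_equal(ic(0, 0, 0, 0)$ic, 0)
  h <- HEADLINE
  v <- ic(h$a, h$b, h$c, h$d)
  expect_equal(v$ic, 3.24137, tolerance = 1e-5)
  expect_equal(v$ic025, 3.14421, tolerance = 1e-5)
  # sanity band around the reference screen's printed 3.17 (formula-variant
  # tolerance, not equality)
  expect_lt(abs(v$ic025 - 3.17), 0.15)
  g <- ic(h$a, h$b, h$c, h$d, method = "gamma_quantile")
  expect_equal(g$ic025, 3.165801, tolerance = 1e-5)
  expect_lt(abs(g$ic025 - 3.17), 0.15)
})

test_that("IC025 < IC for both credibility-bound methods across random tables", {
  set.seed(99)
  for (i in 1:200) {
    cells <- as.list(sample(0:50, 4, replace = TRUE))
    names(cells) <- c("x", "b", "c", "d")
    v1 <- do.call(ic, cells)
    v2 <- do.call(ic, c(cells, method = "gamma_quantile"))
    expect_lt(v1$ic025, v1$ic)
    expect_lt(v2$ic025, v2$ic)
  }
})

test_that("the conjunctive signal rule reproduces reference classifications", {
  expect_true(classify_signal(1437, 9.61, 10.01, 3.17))
  # one strong metric is not enough: n = 1 fails the minimum-count rule
  expect_false(classify_signal(1, 18.50, 18.51, -2.36))
  # PRR/ROR below 2 fails even with IC025 above 0
  expect_false(classify_signal(193, 1.51, 1.51, 0.38))
  # monotone: scaling a up at fixed proportions never flips positive -> negative
  base <- c(a = 12, b = 988, c = 1000, d = 199000)
  was_positive <- FALSE
  for (k in c(1, 2, 5, 10, 50)) {
    cl <- classify_signal(base["a"] * k,
                          prr(base["a"] * k, base["b"] * k, base["c"] * k, base["d"] * k),
                          ror(base["a"] * k, base["b"] * k, base["c"] * k, base["d"] * k),
                          ic(base["a"] * k, base["b"] * k, base["c"] * k, base["d"] * k)$ic025)
    if (was_positive) expect_true(cl)
    was_positive <- was_positive || cl
  }
  expect_true(was_positive)
})

test_that("ror_from_prr back-solves printed rows and rejects impossible input", {
  expect_equal(round_half_up(ror_from_prr(1437, 32457, 9.61), 2), 10.01)
  expect_equal(round_half_up(ror_from_prr(84, 7283, 2.47), 2), 2.49)
  expect_error(ror_from_prr(50, 100, 0.1), "inconsistent")
  # at prr = 1 the back-solved comparator proportion equals the drug's own,
  # so the implied ROR is exactly 1; above 1 the odds transform amplifies
  expect_equal(ror_from_prr(10, 100, 1), 1)
  expect_gt(ror_from_prr(10, 100, 3), 3)
})

test_that("sign concordance and comparator scaling hold on a sampled grid", {
  set.seed(7)
  a <- sample(1:20, 500, TRUE); b <- sample(1:20, 500, TRUE)
  cc <- sample(1:20, 500, TRUE); d <- sample(1:20, 500, TRUE)
  p <- prr(a, b, cc, d); r <- ror(a, b, cc, d)
  expect_true(all(sign(r - p) == sign(p - 1) | abs(p - 1) < 1e-12))
  for (k in c(0.5, 3)) {
    expect_equal(prr(a, b, cc * k, d * k), p)
    expect_equal(ror(a, b, cc * k, d * k), r)
  }
})

test_that("build_table agrees with the brute-force counting oracle", {
  res <- generate_icsr(small_profile(n_reports = 400, seed = 21))
  db <- res$db
  smq <- load_smq()
  for (drug in c("omalizumab", "dupilumab", "backgrounddrug01")) {
    for (pt in c("anaphylactic reaction", "headache")) {
      t <- build_table(db, drug, pt, "all_drugs")
      expect_equal(c(a = t$a, b = t$b, c = t$c, d = t$d),
                   brute_force_cells(db, drug, pt))
    }
    tm <- build_table(db, drug, smq, "all_mabs")
    expect_equal(c(a = tm$a, b = tm$b, c = tm$c, d = tm$d),
                 brute_force_cells(db, drug, smq$pt_terms, comparator = "all_mabs"))
  }
})

test_that("screen output is complete, deterministic and well-ordered", {
  db <- toy_db()
  smq <- load_smq()
  res <- screen_signals(db, "x", smq)
  # one aggregate row plus the single PT with a >= 1
  expect_equal(nrow(res), 2)
  expect_setequal(res$event_label,
                  c("anaphylactic reaction (smq)", "anaphylactic reaction"))
  expect_equal(res$prr, c(1, 1))
  expect_false(any(res$signal_positive))

  gen <- generate_icsr(small_profile(n_reports = 2000, seed = 8))
  drugs <- c("omalizumab", "dupilumab")
  s1 <- screen_signals(gen$db, drugs, smq)
  s2 <- screen_signals(gen$db, drugs, smq)
  expect_identical(s1, s2)
  # ordering: drug blocks in input order, descending a within block
  for (dg in drugs) {
    block <- s1[s1$drug == dg, ]
    expect_true(all(diff(block$a) <= 0))
  }
  # every row's cells sum to the comparator universe size
  expect_true(all(s1$a + s1$b + s1$c + s1$d == n_total(gen$db)))
})

test_that("a mAb-specific planted signal attenuates under the mAb comparator", {
  # plant a signal on one mAb while the other mAbs share an elevated
  # background for the same PT: the all-drugs track sees a strong signal,
  # the all-mabs track a weaker one
  catalog <- tibble::tibble(
    drug_name = c("mab1", "mab2", "mab3", "plain1", "plain2"),
    prob = c(0.2, 0.2, 0.2, 0.2, 0.2),
    is_mab = c(TRUE, TRUE, TRUE, FALSE, FALSE)
  )
  cfg <- generator_config(
    n_reports = 30000, drug_catalog = catalog,
    event_backgrounds = c("anaphylactic reaction" = 2e-3, "headache" = 0.2),
    signal_matrix = tibble::tibble(
      drug_name = c("mab1", "mab2", "mab3"),
      pt_term = "anaphylactic reaction",
      rho = c(8, 4, 4)
    ),
    fallback_event = "headache",
    seed = 31
  )
  db <- generate_icsr(cfg)$db
  t_all <- build_table(db, "mab1", "anaphylactic reaction", "all_drugs")
  t_mab <- build_table(db, "mab1", "anaphylactic reaction", "all_mabs")
  expect_gt(prr(t_all), prr(t_mab))
})
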