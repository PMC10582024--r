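---
title: "Methods: disproportionality screening of spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem and the counting unit

Spontaneous adverse-event reporting systems collect individual case safety
reports (ICSRs): one report describes one patient, one or more drugs (each
with a role code — suspect, concomitant, or interacting), and one or more
adverse events coded as MedDRA preferred terms (PTs). Reporting is voluntary
and denominators of exposure are unknown, so incidence cannot be estimated;
what can be measured is *disproportionality* — whether a drug–event pair is
reported more often than expected if drug and event were independent within
the same database.

Everything in `pvsignal` counts **reports**, never patients and never event
mentions. A report listing a drug twice, or two matching query terms,
contributes once to any cell it falls in. This is why the per-term
breakdowns of `case_term_breakdown()` may sum past the report-level case
count of `classify_reports()`.

## Case definition

A standardized MedDRA query (SMQ) in narrow scope is a high-specificity set
of PTs defining a clinical concept. The bundled anaphylaxis definition has
ten PTs (anaphylactic reaction, anaphylactic shock, anaphylactic transfusion
reaction, anaphylactoid reaction, circulatory collapse, Kounis syndrome,
procedural shock, shock, shock syndrome, type 1 hypersensitivity). Matching
is exact label matching after case and whitespace normalization; no
LLT-to-PT rollup or hierarchy navigation is attempted, because the analysis
operates entirely at PT level. The bundled reference screen
(`reference_screen()`) lists two PTs — "anaphylactoid shock" and "shock
symptom" — that are absent from this ten-term definition. The two lists are
shipped as they stand; the package does not guess which produced which, and
its own screens use the ten-term file (replaceable by any licensed SMQ in
the same CSV dialect).

## The 2×2 table and its conventions

For drug *i* and event *j*, cell A counts reports carrying both, B the
drug's remaining reports, C the event's reports among the comparator, D the
rest. Three conventions matter and are all configurable:

* **Role filter.** Disproportionality cells use reports where the drug is
  *suspect or interacting* (concomitant mentions are treated as
  unexposed). Descriptive tables use all three roles. These defaults mirror
  standard practice: causality assessment should not credit a drug that was
  merely co-administered, while descriptive reporting should not hide
  reports on a technicality.
* **Comparator.** `all_drugs` takes every report in the database as the
  universe; `all_mabs` restricts it to reports carrying at least one
  catalog-flagged monoclonal antibody with a qualifying role. The same role
  filter defines universe membership in both tracks so that
  A + B + C + D always equals the universe size. The dual track exists
  because anaphylaxis is a class effect of therapeutic antibodies: a signal
  that survives the within-class comparison is more informative than one
  driven by the class itself.
* **Exclusion.** The drug's own (role-filtered) reports are removed from
  the comparator cells. A report carrying the drug only as concomitant is
  *not* exposed and therefore stays in the comparator.

## Estimators

With the cells in hand, PRR and ROR are evaluated exactly per their
formulas, with **no continuity correction**. Zero cells produce an `NA`
("undefined metric") rather than an error or a silently corrected value; a
Haldane-corrected companion (`ror_corrected()`, 0.5 added to every cell) is
available and always labelled as such. An undefined metric can never make a
pair signal-positive.

The information component uses the shrinkage observed/expected estimator
IC = log₂((O+0.5)/(E+0.5)), O = A, E = (A+B)(A+C)/N — the operational form
for very large databases, whose ±0.5 shrinkage keeps every cell admissible
(A = E = 0 gives IC = 0 exactly). Two credibility-bound variants are
provided and must satisfy the same property suite:

* `approx` (default): IC₀₂₅ = IC − 3.3(O+0.5)^(−1/2) − 2.363(O+0.5)^(−3/4),
  the published closed-form approximation;
* `gamma_quantile`: log₂ of the exact 2.5% posterior quantile,
  `qgamma(0.025, shape = O + 0.5, rate = E + 0.5)`.

For the largest reference cell (A = 1437) the two differ by ~0.02 bits; both
sit within ±0.15 bits of the reference screen's printed IC₀₂₅, which is the
sanity band used in tests — printed IC values from other implementations are
never asserted as equalities because the credibility-bound variant used
there is not documented.

The signal rule is **conjunctive**: A ≥ 3 and PRR ≥ 2 and ROR ≥ 2 and
IC₀₂₅ ≥ 0. The prose convention this implements could also be read as
requiring only PRR and ROR; the conjunctive reading is adopted because it
reproduces exactly the four flagged rows of the bundled reference screen and
no others, which the acceptance suite verifies.

`ror_from_prr()` inverts the PRR formula to the comparator proportion and
re-expresses it as an odds ratio. It exists purely as an
internal-consistency oracle over printed tables: published (count, total,
PRR) triples imply the published ROR to two decimals without database
access. At PRR = 1 the construction returns exactly 1 (the back-solved
comparator proportion coincides with the drug's own).

## Display and rounding

Ratios are displayed at 2 decimals and percentages at 1 decimal, rounded
half **away from zero** (`round_half_up()`), not banker's rounding —
matching how published safety tables are printed. Emitted percentages are
pure functions of the emitted counts, so re-deriving them from any output
CSV reproduces them exactly.

## Descriptive tables

`demographics_table()` stratifies all reports and case reports by sex, age
band, reporter, continent, and year, with single-row serious and death
strata and non-exclusive condition and per-drug blocks. Every field carries
an explicit `unknown` level so exhaustive blocks sum to the full
denominator. Deaths are the report-level union of a fatal outcome and a
death seriousness category: the two granularities are inconsistent in
published tables, and the union is the safer report-level definition.

`seriousness_table()` scopes to each drug's **serious case reports** —
seriousness blocks in published tables cover serious cases regardless of
signal status, and their denominators are rarely printed, so the denominator
is emitted on every row. The seriousness-category block is multi-select
(a report may be both hospitalized and life-threatening) and may sum past
its denominator; outcome, action and dechallenge blocks are single-select
and sum exactly.

## The synthetic generator

`generate_icsr()` emulates the structure the analysis assumes, with full
ground-truth bookkeeping:

* per report, 1–4 drug mentions from catalog selection probabilities, a
  role per mention, demographics from categorical marginals;
* per PT, inclusion with probability `background × m`, where `m` is the
  largest planted relative reporting rate ρ among the report's
  suspect/interacting drugs for that PT (ρ = 1 everywhere is the null);
  concomitant mentions never transmit ρ, so role handling is testable end
  to end;
* seriousness drawn conditionally on case status, then categories, outcome,
  action and dechallenge fields from their own distributions.

Signals are planted multiplicatively on the per-event inclusion
probability, so in the rare-event limit the expected PRR approximately
equals ρ; the approximation degrades as `background × ρ` approaches 1, and
configurations that would push it past 1 are rejected naming the offending
pair. Ground truth records the realized cells for every planted pair via an
independent set-arithmetic pass over the raw draws, so analysis-side
counting can be checked exactly.

`default_biologics_profile()` encodes the study conditions of the biologics
screen: demographic marginals matching the published all-report margins
(60.9% female, 31.9% physician-reported, 80.8% Americas, ...), the five
biologics flagged as mAbs with selection shares proportional to their
published report totals, anaphylaxis PT backgrounds at realistic orders
(4.6 × 10⁻³ for anaphylactic reaction, matching the large-database rate),
and planted ρ echoing the published effect sizes (9.6, 6.1, 4.9, 2.5, 0.4).
Two deliberate departures from realism, both documented choices: biologics
jointly receive ~30% of drug mentions (their real share of a global
database is ~0.3%, which would need hundreds of millions of simulated
reports), and years at or before 2015 are pooled on 2015. Five background
drugs are also flagged as mAbs so the restricted comparator has a universe.

Two emergent behaviours of this profile are worth knowing. First, because
several drugs carry planted signals on the *same* PT, each drug's
comparator is contaminated by the others' excess reports — the screened PRR
for mepolizumab (ρ = 2.5) is attenuated below 2.5. This is real *masking*
bias, not a defect, but it means `expected_prr = rho` in the ground truth
holds only when a PT carries a single signal. The
`planted_recovery_profile()` used for calibration checks therefore isolates
each ρ on its own drug and PT (drug selection probability 0.12, background
2 × 10⁻³, sized so the expected A exceeds 50 at ρ = 2 with 200,000
reports). Second, a planted signal needs enough reports to clear the
conjunctive rule: at 20,000 reports the benralizumab pair (ρ = 4.9) shows
PRR > 2 but only ~7 reports, and its IC₀₂₅ stays below 0.

What the generator does **not** emulate: temporal reporting dynamics (Weber
effect), duplicate reports, stimulated reporting, correlated
drug–demographic structure, or modeled masking. Passing tests on synthetic
data therefore demonstrate the *estimators and plumbing* are correct under
the stated model, not that real-database artefacts are handled.

Generation is vectorized from a single seeded stream (`set.seed` once per
run): a fixed seed reproduces the database byte for byte, which is the
determinism contract the pipeline tests assert end to end. Per-report
counter-derived substreams were considered and rejected: without
parallelism they buy nothing and would force per-report loops.

## Problem sizes and numerical tolerances used in the test suite

* Brute-force per-report counting oracle: 1,000-report databases, all
  drug–PT pairs.
* Sign-concordance of (ROR − PRR) with (PRR − 1) and invariance of both
  ratios under comparator scaling: exhaustive over all 2×2 tables with
  cells 1–20.
* IC large-count limit 2^IC → A·N/((A+B)(A+C)): relative error < 0.1%
  asserted at A ≥ 10⁴ on proportionally scaled tables.
* Parameter recovery: ρ ∈ {2, 5, 10} on 200,000 reports, screened PRR
  within 3 Monte-Carlo standard errors (delta-method SE on the log scale);
  positivity is additionally asserted only for ρ ≥ 5, since ρ = 2 sits on
  the decision boundary.
* Null false-positive rate: 50,000 reports, ρ ≡ 1, both comparator tracks,
  rate < 1% of screened pairs.
* End-to-end byte-reproducibility: 100,000 reports, simulate → screen →
  tables twice.

## Known limitations

* No empirical-Bayes (GPS/MGPS) scoring and no multiplicity adjustment
  across pairs — deliberately, as the implemented screen applies none.
* Exact label matching means misspelled or translated PT labels silently
  fail to match; the mini term dictionary is a stand-in, not MedDRA.
* The reference drug totals printed in descriptive and disproportionality
  contexts of published screens can differ (all-role versus filtered
  counting); the package exposes both counts rather than reconciling them.
* `NA` metrics propagate as "not positive" rather than as a distinct
  tri-state signal status.
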