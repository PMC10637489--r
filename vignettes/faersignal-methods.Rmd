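---
title: "Methods: disproportionality screening, onset modelling, and the synthetic report generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening, onset modelling, and the synthetic report generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

# The analysis model

`faersignal` implements a case/non-case disproportionality study on
spontaneous-report data. The data model is the FAERS quarterly extract: a
DEMO table with one row per *report version* (`primaryid`) belonging to a
*case* (`caseid`), and child tables for drugs, reactions, therapy dates,
indications, and outcomes. Three modelling commitments shape everything
downstream:

1. **Counting unit.** All 2×2 tables count distinct (report, PT) records,
   not reports. A report listing three distinct PTs contributes three
   records; duplicate PT mentions within a report collapse to one. The
   drug's record total is therefore `a + b`, and `N = a + b + c + d` is
   the record total of the whole deduplicated database.
2. **One report version per case.** Quarterly extracts re-publish earlier
   case versions, so before any counting the DEMO table is reduced to one
   row per case: the row maximizing `(fda_dt, primaryid)`
   lexicographically. This single-pass maximization is equivalent to the
   two-step rule "latest receive date, then highest report id" and is
   idempotent; `primaryid` is compared numerically whenever all ids are
   digit strings, defensively as text otherwise.
3. **Primary-suspect restriction.** A report belongs to the target-drug
   cohort only if a drug row matches the query *and* carries a kept role
   code (`PS` by default). Matching is exact on a normalized token
   (uppercase, whitespace collapsed, trailing period-delimited
   formulation qualifiers removed) against `DRUGNAME` and `PROD_AI` —
   never substring matching, which would conflate combination products.

## The four estimators and their criteria

For each table the package computes (`signal_stats()`):

* ROR `= ad/(bc)`, CI `exp(ln ROR ± 1.96 s)` with
  `s = sqrt(1/a + 1/b + 1/c + 1/d)`; positive if the lower bound
  exceeds 1 and `a >= 3`.
* PRR `= a(c+d)/(c(a+b))` with the uncorrected chi-squared
  `(ad-bc)^2 N / ((a+b)(c+d)(a+c)(b+d))`; positive if PRR ≥ 2, χ² ≥ 4,
  and `a >= 3`. No Yates correction is applied — the criterion thresholds
  were calibrated for the uncorrected statistic.
* IC `= log2(aN/((a+c)(a+b)))`, positive if IC025 > 0.
* EBGM `= aN/((a+c)(a+b))` with `EBGM05 = exp(ln EBGM − 1.96 s)`,
  positive if EBGM05 > 2.

A term is *retained* only when all four flags hold simultaneously; the
ranked deliverable additionally requires `a > 30` and orders by EBGM05
descending (ties: larger `a`, then term name).

Two deliberate simplifications deserve emphasis, because both names carry
Bayesian connotations that the formulas here do not:

* **IC variance.** The BCPNN literature derives the IC's credibility
  interval from a Dirichlet posterior. Here `IC025 = IC − 2·s/ln 2` — a
  delta-method spread on the log₂ scale using the same `s` as the ROR.
  It is deterministic, uses only the four cells, and is conservative
  (wider than the posterior interval at moderate counts). The screening
  consequence is mild: IC025 > 0 becomes approximately `EBGM05' > 1` on
  a slightly different bound.
* **EBGM without shrinkage.** The estimator labelled EBGM is the raw
  observed-to-expected ratio `aN/((a+c)(a+b))` with a log-normal lower
  bound, not a fitted gamma–Poisson mixture posterior mean. True MGPS
  shrinkage requires fitting a mixture across the whole database and is
  out of scope; the raw ratio with the EBGM05-style bound preserves the
  ranking role of the statistic. By construction `2^IC = EBGM` exactly,
  which the test suite asserts as an invariant.

**Zero cells.** Any zero cell leaves the affected estimators `NA`
("undefined"), and undefined estimators yield negative criterion flags.
A Haldane +0.5 correction is available (`haldane = TRUE`) but off by
default, so that published tables — which are computed on uncorrected
counts — can be reproduced exactly.

**Which N?** The estimators depend on the database total only through
`c` and `d`. Published signal tables typically print `a`, ROR, PRR, χ²,
IC, and EBGM without stating the record basis, and those printed values
are not always mutually consistent under a single `N`. The package keeps
`N` explicit (it is whatever the supplied pair database implies), and the
acceptance checks rely only on N-free identities: with `a` and `b` fixed,
any table constructed with `d = ROR·b·c/a` has
`PRR = (a + ROR·b)/(a + b)` regardless of `c` — the bridge from printed
(a, ROR) pairs to printed PRRs, verified as a property test over random
`c`.

## Cohort tables

Demographic summaries normalize age to years (DEC ×10, YR ×1, MON ÷12,
WK ÷52, DY ÷365.25, HR ÷8766) and weight to kg (LBS ×0.4536, GMS ÷1000).
Bands follow the subgroup definitions: age <18 / 18–64 / >64 (18 and 64
inclusive in the middle band), weight <80 / 80–100 / >100 kg (80 and 100
in the middle band). Missing values form explicit "Unknown" rows so each
single-valued characteristic sums to the report total. Outcome
percentages are the one exception: a report may carry several outcome
codes, and published FAERS summaries quote each code's share of all
outcome *entries*, so the outcome block uses that denominator.

Indication exclusion removes event PTs that merely restate the treated
condition. The default exclusion set is every PT observed in the INDI
rows of the target cohort ("auto"); an explicit list can be supplied
instead. The global-set choice (rather than per-report removal) was made
because a tumour-type PT reported as an adverse event is uninformative
for this design whether or not that particular report also lists it as
the indication.

## Time-to-onset

TTO = `EVENT_DT − START_DT` in whole days, using the earliest
full-precision therapy start among the target drug's own therapy rows
(earliest exposure is the conservative choice when several courses are
recorded; non-target drugs' therapy rows never contribute). Partial
dates (YYYYMM / YYYY), missing dates, and negative delays are excluded
and tallied separately; the tallies plus the retained count always equal
the cohort size. Day-0 delays are genuine (onset on the day of
administration) and are retained.

The Weibull fit is maximum likelihood (via `fitdistrplus`) on the delays
with zeros mapped to 0.5 day, since the likelihood requires positive
support; the number of adjusted values is recorded. Confidence intervals
are normal approximations on log(α) and log(β), exponentiated, which
guarantees positive bounds. The shape CI classifies the hazard: upper
bound < 1 → *early* failure (decreasing hazard), lower bound > 1 →
*wear-out*, otherwise *random*. Quantile summaries use the standard
linear-interpolation convention (`stats::quantile` type 7), and the
monthly histogram uses 30-day bins (`[30(k−1), 30k)`, day 0 in month 1,
open tail beyond 360 days) — calendar months would change the published
percentage arithmetic without adding information. Note that a
right-skewed median can sit well below the fitted Weibull's implied
median; the two statistics are computed independently and no
reconciliation is attempted.

No censoring model is used: reports without a usable onset are excluded,
not treated as right-censored, matching how such analyses are published.

## Subgroups and sex differences

"Subgroup disproportionality" is only well defined if the comparator
moves with the subgroup, so `subgroup_signals()` re-runs the complete
four-algorithm screen inside each stratum's own database slice (both the
target drug and the background restricted to the stratum). Reports with
an unknown stratum value are excluded from that stratification entirely.

The sex-difference analysis conditions on the target drug: for each PT
with ≥ 3 cohort cases it compares female vs male records *within* the
cohort, giving a female-over-male ROR with the usual log-normal CI. The
p-value is a two-sided Fisher exact test for every PT regardless of cell
size — uniform and exact, avoiding a cell-size branch — and p-values are
Benjamini–Hochberg adjusted across all tested PTs (`stats::p.adjust`).
Volcano coordinates are `x = log2(ROR)`, `y = −log10(p_adj)`, labelled
significant at `p_adj < 0.05`; the threshold is this package's choice,
declared rather than inherited. Swapping the sex labels inverts the ROR
and negates `x` exactly, which is asserted as a property test.

# The synthetic generator

Real quarterly extracts are large and carry no ground truth, so the
package ships a generator whose output is structurally FAERS-like and
whose answers are known in advance. Per report it draws:

* a drug set (independent inclusion by catalog prevalence; a drug is
  forced — prevalence-weighted, independently of events — into the ~10%
  of reports that would otherwise be empty), exactly one PS role, and
  free-text name variants (case changes, brand synonyms, stray
  whitespace, trailing ". INJECTION" qualifiers);
* reaction PTs, each with probability `baseline(E)`, multiplied by the
  planted `λ` (capped at 1, with a warning) in reports containing a
  planted drug; optional female-specific multipliers support
  sex-difference validation, and a planted signal may be restricted to
  one age stratum;
* therapy starts per drug and an event date equal to the PS drug's start
  plus `floor(Weibull(scale = 38.56 d, shape = 0.55))` — the onset lag
  profile of a cytotoxic drug, heavily front-loaded;
* demographics from categorical distributions chosen to resemble an
  oncology cohort (48% male, 40% female, 12% unknown; 20% children, 45%
  adults, 20% elderly, 15% unknown; 65% of weights missing; mostly
  health-professional reporters);
* missing event dates (default 50% — onset analyses in this field
  typically retain only a quarter of reports), partial dates (5%,
  encoded as YYYYMM or YYYY truncations, the FAERS dialect), and
  duplicate case versions (10%, re-emitted with a higher `primaryid` and
  a later-or-equal `fda_dt`, with the intended dedup survivor recorded).

The PT catalog spans 63 PTs in 16 SOCs with baselines from 0.0025 to
0.15 per report (sum ≈ 1.9, a realistic mean reaction count); the drug
catalog holds 12 oncology-adjacent drugs. Defaults plant six
etoposide–event associations with λ between 5 and 15. All randomness
flows from a single integer seed (`withr::with_seed`), and generation is
exactly reproducible.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: reactions are conditionally independent
given exposure (no event co-reporting correlations, no syndromes);
drug-name noise is limited to case/whitespace/qualifier variants (no
misspellings, no combination-product strings); reporting propensities do
not drift over calendar time; duplicates are exact copies rather than
partially updated resubmissions; and the indication field is drawn
independently of the reaction list. Signal recovery on this generator
validates the machinery, not the epidemiology.

A note on recovery: with the PS-role restriction, reports containing the
planted drug as a non-suspect fall into the comparator with elevated
event rates, so downstream estimators recover `λ` diluted by roughly the
non-suspect share — the test suite therefore checks factor-2 recovery of
`λ` under an all-roles query and band recovery (ROR in [5, 20] for
λ = 10) under the PS default.

# Problem sizes and runtime choices

The test suite exercises the stack at sizes chosen to make stochastic
assertions stable while keeping a full run around fifteen seconds:
null-calibration and planted-recovery runs use 20,000-report databases
(~46,000 pairs, ≥ 700 drug–PT combinations); Weibull recovery uses 20
replicates of n = 2,000 plus a single n = 2,138 draw matched to the
published onset sample; the sex-null simulation uses 500 PTs over 3,000
reports. False-positive calibration asserts ≤ 5% of null pairs passing
the four-way screen and ≤ 10% passing the ROR criterion alone, both under
fixed seeds.

# Known limitations

* No gamma–Poisson shrinkage and no Dirichlet-posterior IC interval (see
  above); both are swappable behind the same column contract.
* No multiple-comparison correction at the screening stage — the
  four-way intersection plus the case minimum is the (field-standard)
  false-positive control; FDR is applied only in the sex-difference
  analysis.
* PT→SOC mapping is a flat two-column table; the MedDRA hierarchy
  (HLT/HLGT/SMQ) is out of scope, as is the pre-2004 legacy schema.
* The pipeline holds all tables in memory; it is sized for single-drug
  cohort studies, not whole-database scans across every drug.
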