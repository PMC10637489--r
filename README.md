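# faersignal

Disproportionality signal detection for FAERS-style spontaneous
adverse-event reports.

Spontaneous reporting systems such as the FDA Adverse Event Reporting
System (FAERS) collect millions of post-marketing safety reports, each
linking the drugs a patient received to the adverse events (MedDRA
preferred terms, PTs) the reporter observed. Because there is no
denominator of exposed patients, safety signals are sought by
*disproportionality analysis*: for a target drug and each event, a 2×2
table of distinct (report, PT) records is formed —

|              | target event | other events |
|--------------|--------------|--------------|
| target drug  | a            | b            |
| other drugs  | c            | d            |

— and the observed reporting rate is compared with the rate expected under
independence. `faersignal` implements the four classical estimators on
this table (N = a + b + c + d):

* **ROR** (reporting odds ratio) = ad/(bc), with 95% CI
  exp(ln ROR ± 1.96·s), s = √(1/a + 1/b + 1/c + 1/d); positive when the
  lower bound exceeds 1.
* **PRR** (proportional reporting ratio) = a(c+d)/(c(a+b)) with the
  uncorrected χ² = (ad−bc)²·N/((a+b)(c+d)(a+c)(b+d)); positive when
  PRR ≥ 2 and χ² ≥ 4.
* **IC** (BCPNN information component) = log₂(aN/((a+c)(a+b))), positive
  when its lower bound IC025 > 0.
* **EBGM** (observed-to-expected ratio with an EBGM-style lower bound)
  = aN/((a+c)(a+b)), positive when EBGM05 > 2.

A signal is retained only when **all four** criteria hold with at least
3 cases. Around this core the package provides the full analysis a
pharmacovigilance study needs:

* parsing of FAERS-style quarterly ASCII tables (DEMO, DRUG, REAC, THER,
  INDI, OUTC; dollar-delimited) and the standard case-version
  deduplication (latest `FDA_DT`, ties to the higher `PRIMARYID`);
* target-drug identification from free-text `DRUGNAME`/`PROD_AI` with
  role-code restriction (primary suspect by default);
* PT→SOC aggregation, indication exclusion, novelty flagging against a
  drug-label PT list, and EBGM05 ranking;
* time-to-onset: therapy-start to event-onset delays with strict date
  cleaning, 30-day binning, and a maximum-likelihood Weibull fit whose
  shape parameter classifies the hazard as early / random / wear-out;
* subgroup screens (age, weight, sex, reporter) and a within-drug
  sex-difference analysis with Fisher exact tests, Benjamini–Hochberg
  FDR, and volcano-plot coordinates;
* a synthetic FAERS-like generator with planted drug–event associations,
  duplicate case versions, and Weibull onset lags, so the entire pipeline
  is testable with known ground truth.

## Worked example

Generate a synthetic database of 20,000 reports in which etoposide is the
primary-suspect drug in ~5% of reports and six drug–event pairs are
planted with relative reporting ratios between 5 and 15, then run the
screen:

```r
library(faersignal)

cfg <- synthetic_config(n_reports = 20000, seed = 1)
reports <- generate_reports(cfg)
dir <- tempfile(); emit_quarterly_files(reports, dir)

db <- assemble_reports(read_quarter(dir))
query <- drug_query(c("ETOPOSIDE", "VP-16", "VEPESID", "TOPOSAR", "LASTET"))
target <- identify_drug_reports(db, query)

stats <- apply_criteria(signal_stats(contingency_counts(
  extract_case_pairs(db), extract_case_pairs(target)
)))
sig <- screen_signals(stats)
#> screen_signals: 6 of 63 terms positive under all four algorithms
rank_and_filter(sig, min_a = 30)[, c("term", "a", "ror", "prr", "ebgm05")]
#> # A tibble: 4 × 5
#>   term                    a   ror   prr ebgm05
#> 1 Ovarian failure        38  8.80  8.69   4.12
#> 2 Febrile neutropenia   202  5.55  5.18   3.58
#> 3 Thrombocytopenia      134  3.38  3.26   2.40
#> 4 Pancytopenia           69  3.39  3.32   2.27
```

All six retained terms are planted signals (the two others fall below the
a > 30 ranking threshold); none of the 57 null terms survive the
four-way screen. The estimates sit below the planted ratios because the
planted drug also appears as a non-suspect drug in comparator reports.
Time-to-onset from the same run:

```r
tto <- compute_tto(target, query)
tto
#> <tto_sample> n = 429 | excluded: missing 458 , invalid 33 , negative 0
fit_weibull(tto)
#> <weibull_fit> n = 429 | scale alpha = 35.21 (29.72-41.71) d |
#>   shape beta = 0.59 (0.55-0.63) | early
```

The fitted shape β < 1 (early-failure pattern, hazard decreasing with
time since therapy start) recovers the generator's Weibull(38.56, 0.55)
onset-lag distribution from the cleaned delays.

`run_pipeline()` executes the same stages end to end from a config object
and writes the demographic table, annual counts, PT/SOC signal tables,
TTO summary, subgroup and sex-difference tables, plus a manifest with
input hashes and every exclusion tally.

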