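# cd4eqa

Scoring and longitudinal analytics for national CD4 external quality
assessment (EQA) programs.

## What this is for

Reliable CD4 T-cell enumeration guides the clinical management of people
living with HIV, and in much of sub-Saharan Africa it is delivered by a
mixed fleet of conventional flow cytometers (FACSCount, CyFlow) and
point-of-care counters (PIMA) in laboratories that are rarely accredited.
A national EQA program ships each participating laboratory a blinded
two-specimen proficiency panel (one low, one mid CD4 level) three times a
year and judges every laboratory against the consensus of its peers.
`cd4eqa` implements such a program's evaluation pipeline end to end, for
program coordinators and for anyone studying proficiency-testing
statistics:

* **Consensus statistics with outlier trimming** — per quantity
  (specimen × marker × percent/absolute), the group mean and sample SD are
  computed, values deviating by more than 2 SD are excluded, and the
  consensus is recalculated once.
* **SDI scoring** — each laboratory's Standard Deviation Index,
  `SDI = (reported − trimmed mean) / trimmed SD`, signed so that + means
  above the group; a quantity is satisfactory when `|SDI| ≤ 2`.
* **Adjudication** — pass / fail (with failing quantities) /
  unable-to-report per laboratory and session.
* **Error-phase taxonomy** — coordinator-recorded failure causes
  classified into pre-analytical, analytical and post-analytical phases,
  with phase and category distributions.
* **Longitudinal trends** — participation, pass/fail/unable rates and
  per-instrument breakdowns across sessions.
* **Reporting** — per-laboratory and coordinator session reports, each as
  deterministic JSON plus plain text.
* **A synthetic program generator** with known ground truth (laboratory
  biases, injected errors by phase, unable events), since real submission
  data are not public.

The package also ships the published per-session, per-instrument
pass/fail counts of the Cameroon national program, 2014–2018
(`cameroon_session_counts()`), which anchor the generator's default
schedule and serve as an exact-arithmetic check of the trend layer.

## Worked example

Six laboratories report a CD4 absolute count; one is grossly off:

```r
library(cd4eqa)

agg <- compute_trimmed_aggregate(c(500, 510, 490, 505, 495, 1200),
                                 lab_ids = sprintf("LAB%02d", 1:6))
agg
#> Trimmed consensus: mean 500, SD 7.906 (n = 5, 1 outlier(s) excluded)
#>   outliers: LAB06

compute_sdi(c(505, 524), agg, lab_ids = c("LAB04", "LAB99"))
#> # A tibble: 2 × 5
#>   lab_id reported_value residual   sdi within_limit
#>   <chr>           <dbl>    <dbl> <dbl> <lgl>
#> 1 LAB04             505        5 0.632 TRUE
#> 2 LAB99             524       24 3.04  FALSE
```

LAB06's 1200 exceeds the initial mean (616.7) by more than twice the
initial SD (285.9), so it is excluded and the consensus becomes
500 ± 7.9.  LAB04 sits 0.63 SD above the consensus and passes; a
laboratory reporting 524 would be 3.04 SDI out and fail that quantity.

The full workflow lives in `analysis/01_simulate.R` … `04_reports.R`:
generate the default 11-session synthetic program, score every session
through the validating file parsers, tabulate trends, and render reports
under `results/`.  For example, step 3 prints (seed 48):

```
simulated program:
  participation: 15 53 51 62 60 57 26 39 51 49 57
  fail % among reporting: 14 50 29 13 14 13 5 19 8 14 16
published counts, reconstructed:
  fail % among reporting: 50 42 27 7 16 7 11 26 10 23 9
```

## Package layout

* `R/` — io/validation, scoring, error taxonomy, trends, reporting,
  synthetic generator, pipeline driver.
* `analysis/` — numbered narrative drivers over the package functions.
* `inst/extdata/cameroon_session_counts.csv` — published session counts.
* `vignettes/eqa-methods.Rmd` — the scoring model, boundary rules,
  generator design and its limitations.
* `tests/testthat/` — unit, property and acceptance suites, including an
  independent brute-force trimming oracle.
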