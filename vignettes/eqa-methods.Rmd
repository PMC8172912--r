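---
title: "Methods: consensus scoring and synthetic program design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus scoring and synthetic program design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cd4eqa)
```

## The scoring model

External quality assessment (EQA) for CD4 T-cell enumeration ships two
blinded stabilized whole-blood specimens — one low and one mid CD4 level —
to every participating laboratory three times a year.  Each laboratory
reports the percentage and absolute count of CD3, CD4 and CD8 T cells on
its own instrument, and is judged against the *consensus* of all
participants rather than against a manufacturer target.

For each measured quantity (session × specimen × marker × value kind) the
package computes:

1. the group mean $\bar{x}$ and sample SD $s$ (denominator $n-1$) over all
   reported values;
2. outlier exclusion: values with $|x_i - \bar{x}| > k\,s$ (default
   $k = 2$) are excluded;
3. one recalculation of $\bar{x}$ and $s$ on the remainder — the *trimmed
   consensus*.

Each laboratory then receives a Standard Deviation Index per quantity,

$$\mathrm{SDI}_i = \frac{x_i - \bar{x}_{trim}}{s_{trim}},$$

whose sign says whether the laboratory reported above or below the group.
Performance on a quantity is satisfactory when $|\mathrm{SDI}| \le 2$.

### Adjudication

A laboratory **passes** a session when it reported results for both panel
specimens and every scored quantity is within the limit.  Any quantity out
of limit makes it a **fail**, with the failing quantities listed.  A
registered laboratory that returned no result at all is
**unable to report** — tracked separately because it reflects stockouts
and instrument breakdowns, not analytic accuracy.  Quantities a laboratory
did not report (a point-of-care counter that yields no percentages, for
instance) are never held against it.

### Boundary and degenerate rules

These cases are under-determined by the verbal rule and are fixed as
follows:

* **Trim boundary is strict, pass boundary inclusive.**  A value at
  exactly 2 SD from the initial mean is *retained* in the consensus
  (exclusion requires "greater than" 2 SD); a score of exactly
  $|\mathrm{SDI}| = 2$ *passes* ("within ± 2").
* **Outlier-trimmed laboratories are still scored.**  Exclusion from the
  consensus is a statistical, not a disciplinary, act: the trimmed
  laboratory receives an SDI against the trimmed consensus and is
  adjudicated by the same rule (in practice it essentially always fails).
* **Unanimous groups.**  If the trimmed SD is 0, exact agreement scores
  SDI 0; any deviation from a unanimous consensus is out of limit and the
  SDI is recorded as a signed infinity sentinel.
* **Small groups.**  A quantity with fewer than `min_group_n = 3` reported
  values is *unscoreable*: no 2-laboratory consensus is ever formed.  A
  laboratory whose only reported quantities are unscoreable passes with
  the note `"unscored"`.
* **Trimming never empties the group.**  A trimming pass that would leave
  fewer than `min_group_n` values is not applied; the statistics are
  emitted from the pre-pass set.
* **Incomplete panels.**  Reporting only one of the two specimens cannot
  be a pass; the verdict is a fail with note `"incomplete_panel"`.
* **Pooled consensus.**  The consensus pools all instrument technologies
  per quantity; technology-stratified peer groups are available via
  `scoring_config(by_instrument = TRUE)` but pooling is the program's
  default rule.
* **Single trim pass.**  The consensus is recalculated once after
  exclusion; `trim_passes` allows iterated trimming for sensitivity
  analyses.

### Tunable parameters

| parameter | units | default | role |
|---|---|---|---|
| `outlier_k` | SD | 2 | consensus trimming threshold |
| `pass_limit` | SDI | 2 | satisfactory-performance limit |
| `min_group_n` | laboratories | 3 | smallest scoreable consensus group |
| `trim_passes` | passes | 1 | compute → exclude → recompute cycles |
| `by_instrument` | — | FALSE | technology-stratified peer grouping |

## Error taxonomy and trends

Failures investigated by the coordinator are recorded as categorized error
records and classified into the pre-analytical (transport/preservation,
identification, request procedure, mix-ups), analytical (reagents,
pipetting and pipette calibration, gating, instrument errors, sample
handling) and post-analytical (paper-form and website data entry,
transcription, reporting omission) phases.  The mapping is total and
fixed; the phase is always derived from the category, never stored.
Distributions count *records*, not laboratories — a failing laboratory may
carry several records.

The trend layer counts verdicts per session: pass/fail percentages are
taken over laboratories *able to report* and the unable-to-report
percentage over all registrants.  Percentages are kept at full precision;
display rounding is half-up to the nearest integer (`round_half_up()`),
the convention of the program's printed tables.  A transcription of the
program's published per-session, per-instrument counts ships with the
package (`cameroon_session_counts()`); only counts are stored, and the
occasional arithmetic slip in the published percentages is deliberately
not reproduced — percentages are always recomputed from counts.

## The synthetic program generator

No raw submissions from the program are public, so the package ships a
generator that produces multi-session programs with known ground truth.
Each reporting laboratory draws every value as

$$x = \text{nominal} \times (1 + b) \times (1 + \varepsilon),$$

with a persistent per-laboratory systematic bias $b$ and within-run noise
$\varepsilon$.  Defaults encode the study conditions of the Cameroon
program wherever those are published, and field-plausible values
elsewhere:

* **Schedule** (`cameroon_program_config()`): 11 sessions; registrants per
  session derived from the published reporter counts inflated by the
  unable-to-report rate; elevated unable rates (30 %, 20 %) in sessions
  7–8, the reagent-stockout sessions; per-session instrument mix equal to
  the published instrument fractions, with the point-of-care (PIMA) share
  rising from 2/14 to 37/54.
* **Panel nominals**: low specimen ≈ 150 CD4 cells/µL, mid ≈ 500 cells/µL
  with fixed CD3/CD8 companions.  These are *declared* defaults — the
  program's true panel targets are not published — and are overridable.
* **Between-laboratory bias**: $b \sim$ Normal(0, 0.08) truncated at
  ±2 SD, plus a small instrument-class offset (CyFlow +2 %, PIMA −2 %).
  An 8 % between-laboratory CV matches what interlaboratory CD4
  comparisons typically show; truncation reflects that gross *persistent*
  miscalibration does not survive in a program with corrective action
  (transient gross errors are injected separately).
* **Within-run noise**: instrument-class repeatability CVs of 1.5–2.5 %,
  of which 70 % of the variance (`noise_cor`) is shared across the twelve
  quantities of a run — one operator, one calibration, one reagent batch
  drive all results of a session.  Without this correlation a moderately
  biased laboratory would fail "some quantity out of twelve" far too
  often, and simulated pass rates fall well below anything the program
  observed.
* **Injected errors**: with per-session probability `p_error` a reporting
  laboratory commits one error whose phase is drawn from
  `phase_mix = (0.175, 0.770, 0.055)`, the program's published error-phase
  distribution.  Pre-analytical errors degrade both specimens' values to
  60 % (sample-integrity surrogate); analytical errors perturb one
  quantity (pipetting/gating surrogate); post-analytical errors swap two
  values or drop a digit (transcription surrogate).  The per-session
  `p_error` schedule declines as the published failure rate declines —
  the corrective-action effect — using the observed failure rate minus
  the ~10 % failure the bias distribution alone produces.
* **Reproducibility**: one seed; each session uses an independently
  derived sub-stream, so any single session regenerates identically in
  isolation.

### What the generator does and does not emulate

It emulates: roster growth, technology shift toward point-of-care
instruments, instrument-specific accuracy and precision, stockout
sessions, declining error pressure, and the published error-phase mix.

It does **not** emulate: correlated errors across laboratories (a bad
panel shipment), drift of a laboratory's bias over time, marker-ratio
constraints beyond CD3 ≥ CD4, non-normal heavy-tailed blunders other than
the three injected surrogates, or corrective-action feedback within a run
of sessions (the declining `p_error` schedule is imposed, not emergent).
Passing tests on synthetic data therefore demonstrate the *scoring
arithmetic and its statistical behaviour* under controlled conditions,
not that real Cameroonian submissions would reproduce the published
figures.

One known mismatch is worth stating: in the earliest sessions (14–15
laboratories, ~45 % error pressure) the simulated failure rate (~30 %)
undershoots the published 50 %, because heavy contamination inflates the
initial consensus SD and a single 2-SD trim cannot remove it — the
masking weakness of non-robust trimming at small $n$.  This is a property
of the scoring rule itself, faithfully implemented; robust alternatives
(median/MAD, ISO 13528 Algorithm A) are deliberately out of scope because
they are not the program's rule.

## Verification strategy and problem sizes

The test suite checks the scoring path against an independent brute-force
trimmer (plain sum/loop arithmetic) exhaustively over all multisets of
size ≤ 8 from a 5-point value grid (1,266 groups) and on randomized
contaminated groups; SDI centring, scale equivariance and translation
invariance over 1,000 random groups; boundary behaviour on both sides of
the trim and pass limits (the exact trim boundary located by root-finding
on the deviation/SD ratio); parameter recovery over 100 seeds (a +30 %
miscalibrated laboratory among 30 must be trimmed and fail; forced-clean
laboratories must pass); recovery of the error-phase mix from 10,000
injected errors to within 1.5 percentage points; a 100-seed harness in
which declining error pressure must yield a declining fitted failure
trend in expectation; and byte-identical reruns of the full
simulate-then-score pipeline.  These sizes keep the whole suite in the
low minutes on a single core while leaving the statistical assertions
comfortable margins.

## Known limitations

* The consensus is as good as the peer group: with three laboratories the
  rule is formally applicable but statistically weak; `min_group_n` only
  floors the group size.
* Scores across quantities of one laboratory are treated as exchangeable
  in adjudication; no multiplicity adjustment is applied (none is part of
  the program's rule).
* The published counts table transcribed into the package contains one
  internally inconsistent row (session 9: instrument cells sum to 5
  failures, the all-instruments column prints 6); the package always
  derives all-instruments rows by summation over instruments.
* Reports are rendered in English only.
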