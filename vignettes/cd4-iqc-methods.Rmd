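---
title: "Statistical methods for CD4 internal quality control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for CD4 internal quality control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cd4iqc)
```

## The two IQC schemes and what they measure

Internal quality control of CD4 enumeration asks a narrow question every
day: is the analytical process behaving as it did yesterday? `cd4iqc`
implements the two schemes a CD4 laboratory can afford to ask it with.

**Duplicate analysis.** A patient sample processed the previous day is
re-tested. Because a sample's true count is (approximately) stable over one
day under proper storage, the two results should differ only by analytical
noise. The acceptance statistic is the signed percent variation

$$\%V = \frac{\text{day-2 count}}{\text{day-1 count}} \times 100 - 100,$$

with $|\%V| \le 20$ acceptable. The boundary is inclusive: only variation
*beyond* ±20% fails. One low (200–400 cells/µL, closed interval) and one
normal (>500 cells/µL, strict) sample are carried over per day; counts in
(400, 500] are eligible for neither level, a deliberate choice since the
conventional windows leave that band undefined. Precision over a period is
summarised by the mean of $|\%V|$ (sign discarded), by the regression
$r^2$ of day-2 on day-1 counts, and by Bland–Altman analysis of the paired
differences.

**Commercial stabilized controls.** A manufactured control with an
assigned mean and range is run daily. The manufacturer's range is wide; a
laboratory should establish its own range as mean ± 2 sample SD — final
after 20 runs, provisional after 10 — and monitor a Levey-Jennings chart of
the daily values under the Westgard multirules. Precision is the monthly
%CV; accuracy is tracked as out-of-range readings.

## Conventions and decisions

Several quantities have more than one textbook form; the package fixes them
as follows and exposes each as a parameter where sensible.

* **Standard deviation** is always the sample SD ($n-1$), the clinical-lab
  (CLSI) convention, appropriate at the small $n$ of QC series.
* **Bland–Altman** differences are day-2 − day-1 (observed − expected),
  matching the %V sign convention, and the limits of agreement use exactly
  ±2 SD rather than ±1.96 (`k_sd` is an argument).
* **Failure rate**: failures are divided by total contributed
  laboratory-months, then expressed per laboratory-year by dividing months
  by 12, because that is the unit the rate is reported in. The literal
  per-month rate is returned alongside (`rate_per_lab_month`), since the
  verbal recipe "failures ÷ total months" taken at face value yields it.
* **Westgard rules**: the classic six (1~2s~ warning; 1~3s~, 2~2s~, R~4s~,
  4~1s~, 10~x~ rejection), each evaluated within one control level and one
  lot — a lot changeover resets the history. Rule thresholds are strict
  inequalities (|z| > 2 etc.) while range limits are inclusive (a value
  exactly at mean ± 2 SD is in range). For failure-*rate* purposes a QC
  failure is an out-of-active-range run; multirule rejections are reported
  but a lone 1~2s~ warning never enters the rate.
* **Ranges in the pipeline** (`analyze_control_stream()`): the first 20
  runs of a lab on a lot are its establishment phase and are judged against
  the manufacturer range; from run 21 the laboratory range takes over and
  z-scores (hence multirules) become available. Short-shelf-life products
  rarely reach that point and stay on the manufacturer range, which is
  exactly the practical limitation that makes them weak for trend
  monitoring. Provisional (10-run) ranges are accepted only on request
  (`use_provisional`, `n_establish = 10`): by default QC decisions wait for
  the final range.
* **Duplicate same-day records** for one lab/level are a data error and are
  flagged invalid rather than averaged; invalid records of any kind are
  kept in place with a reason, so pass + fail + invalid always partitions
  the input.
* **Table-style reporting** rounds %V and %CV to 1 decimal, $r^2$ to 2 and
  Bland–Altman to 2, with an en-dash sentinel for unavailable cells; the
  machine-readable table keeps full precision, so the printed report can
  never drift from the kernel statistics.

## The synthetic laboratory network

No multi-laboratory CD4 QC dataset is publicly deposited, so the package
ships a generator whose defaults describe a realistic network — and those
defaults are fixed study conditions, not tuning knobs.

`default_study_config()` builds 11 laboratories over calendar year 2013:
three FACSCount, five FACSCalibur and three Cyflow instruments, each
testing the first 20 days of every month, six labs additionally running a
commercial control (one IMMUNO-TROL with ~90-day lots, five Multi-Check
with ~30-day lots; manufacturer ranges ±20% of the assigned mean). Each
lab's analytical CV is derived from the mean $|\%V|$ values observed across
such networks (0.5–7.2%) through the half-normal identity for the
difference of two independent CV-level Gaussian errors,
$E|\%V| \approx \tfrac{2}{\sqrt\pi} \cdot 100\,cv$, giving CVs of roughly
0.4–6.4%. Reported field %CVs of commercial controls span 2.2–12.5% and are
used as the recovery test points; where the two precision columns disagree
for a lab, the duplicate-analysis figure defines its CV, since duplicate
analysis is the scheme under study.

The error model is Gaussian on the relative scale: a measurement is
`true × (1 + N(bias, cv))`, matching the %CV framing of instrument
imprecision (a lognormal switch exists for skeptics of negative-tail
symmetry). True counts are uniform over each level's window (low
[200, 400]; normal [500, 1200], a ceiling spanning the range CD4 duplicate
plots typically cover) — no patient-mix or treatment-trajectory modelling
is attempted. Day-1 and day-2 measurements are conditionally independent
given the true count; overnight degradation can be emulated with a day-2
bias but is off by default, as stored samples are treated as stable.
Counts are rounded to integers as instruments report them, and statistics
run on the rounded values; `round_counts = FALSE` exists for algebraic
tests. Draws that would round to a non-positive count are resampled and
logged, never silently clipped.

Out-of-control events are multiplicative: a *shift* multiplies affected
measurements by $1 + m$ for its duration, an *outlier* does so for one
day, and a *drift* applies $1 + m\,(d - \text{onset} + 1)$ so the first
affected day already carries one day's drift. Events target the day-2
measurement of the duplicate stream and/or the control measurements —
day 2 is where a fresh analytical problem shows up against a day-1 baseline.
`ground_truth()` returns the configured CVs, the event table and the exact
number of duplicate failures the events would cause at cv = 0, enabling
closed-loop recovery tests. Streams are deterministic in the seed; the
control stream uses seed + 1 so neither stream depends on generation order.

What passing tests on this generator do **not** show: robustness to
non-Gaussian error, carry-over correlation between days, patient-mix
drift, or instrument-specific artefacts (e.g. gating failures on stabilized
blood). The generator validates the *statistics*, not the cytometry.

## Numerical behaviour and verification

Every kernel statistic is cross-checked in the test suite against an
independent brute-force implementation — explicit loops over the
definitions — to 10⁻⁹ relative tolerance on randomized fixtures, and the
Westgard engine against a literal window scan. Degenerate inputs error
informatively rather than returning silent zeros: %V with a non-positive
day-1 count, %CV with fewer than two values or non-positive mean, $r^2$
with zero variance, ranges from too few runs (a zero-spread establishment
set is flagged degenerate). Daily cross-lab SE is undefined with a single
lab and is `NA`, never 0; days without observations are omitted, never
zero-filled.

Three calibration facts the acceptance checks lean on, all consequences of
the Gaussian model rather than fitted numbers: an in-control run falls
outside its laboratory ±2 SD range with probability ≈ 4.6% and beyond 3 SD
with ≈ 0.27%; a +3 SD step shift is rejected by the multirules within four
runs in ≳ 98% of series even with a range estimated from 20 runs; and over
three months of duplicate pairs at the worst plausible analytical CV
(7.2%), the regression of day-2 on day-1 counts across the full low + normal
span gives $r^2$ well above 0.8. The last point deserves its footnote: with
day-1 counts restricted to the low window alone, between-sample variance
($200^2/12$) against 7.2% noise caps $r^2$ near 0.77, so long-term-precision
$r^2$ is meaningful only when the duplicate series spans the eligibility
windows — which is how the package computes it.

Problem sizes in the shipped tests — a 1,000-series shift-detection study,
100,000 simulated LJ runs, an 11-lab study year — were chosen so the whole
suite completes in well under a minute while keeping Monte-Carlo error an
order of magnitude inside each asserted band.

## Known limitations

* Failure *rates* depend strongly on the active-range convention: a
  laboratory ±2 SD range has a built-in ~4.6% false-alarm rate per run, so
  its failures per laboratory-year scale with testing frequency and are not
  comparable to manufacturer-range failure counts without that caveat.
* The generator's uniform true-count model makes $r^2$ optimistic relative
  to a clinic whose patients cluster tightly within a window.
* Multi-analyte panels (CD3, CD45), EQA scoring, and instrument acquisition
  quality are out of scope; the package sees counts, not cytograms.
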