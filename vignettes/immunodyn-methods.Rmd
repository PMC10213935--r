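---
title: "Methods: dynamic networks and hypergraphs for multi-compartment mediator time courses"
author: "immunodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic networks and hypergraphs for multi-compartment mediator time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunodyn)
```

## The data model

The unit of observation is one concentration of one mediator
(a cytokine, chemokine or growth factor from a multiplex immunoassay
panel) in one tissue compartment of one subject on one study day.
`MediatorExperiment` stores these as a `SummarizedExperiment`: rows are
the panel mediators, columns are `{group, subject, compartment, day}`
samples, and the single `concentration` assay holds non-negative values
(`NA` = missing) in panel units — `pg/mg protein` for tissue
homogenates, `pg/ml` for blood. Two invariants are enforced at
construction and never repaired silently: sample keys are unique, and
every day belongs to the declared sampling schedule. Days are calendar
study days, not indices, because realistic schedules are unevenly
spaced (the bundled 11-day rat-style schedule has a nine-day gap
between days 11 and 20) and every trend statistic in the package
correlates against real time.

Two reference panels are bundled: the 27-analyte rat bead set and the
26-analyte human set. Replicate aggregation (`aggregateTimeCourse`)
defaults to the mean, matching the usual "mean ± SEM" presentation of
multiplex data; the median is available. Cells with no replicates stay
`NA` with a recorded count of zero — no imputation, including no
below-detection-limit substitution, since the downstream statistics all
delete missing values pairwise.

## Spearman cross-correlation census

All `(mediator, compartment)` variables are correlated pairwise with
midrank Spearman ρ; observations are samples aligned by exact
`{group, subject, day}` key, pooling all time points and subjects of
the selected groups. Whether multi-subject cohorts should be pooled or
correlated per subject is genuinely open; pooling is the default
because the census is descriptive (a count of co-moving pairs, not an
inference about any one subject) and because it keeps panels from
different groups on a common footing. The choice is recorded in the
result's metadata.

The default p-value is the t approximation
\(t = \rho\sqrt{(n-2)/(1-\rho^2)}\) on \(n-2\) df, chosen for
comparability with the standard census tools; an exact permutation
p-value is available behind a flag for \(n \le 9\). No correction for
the number of pairs is applied by default — the census summary
(`percentSignificant`) is deliberately a raw p < 0.05 count over
possible pairs — with Benjamini–Hochberg available for uses that need
error control. Pairs with fewer than 3 paired observations are flagged
missing and leave both the numerator and the denominator. Heatmap
display uses average-linkage clustering on the 1 − ρ distance and a
colour scale fixed to [−1, 1] so group panels are comparable.

## Dynamic Network Analysis (DyNA)

DyNA asks how the mediator co-expression network changes along an
ordinal axis — rejection-severity grades or time bins. For each pair of
consecutive strata, all samples carrying either label are pooled and an
undirected edge joins mediators whose |Pearson r| reaches 0.90 (a
conventionally stringent "move in parallel" cutoff; the comparison is
≥). Because ordinal strata, unlike time, give no within-sample
trajectory, correlation across the interval's samples is the only
self-consistent reading of "trajectories in parallel", and it matches
how interval-pooled dynamic networks are built in prior work. Each
network is scored by

\[ \text{complexity} = \frac{N_1 + N_2 + \cdots + N_n}{n-1} =
   \frac{2\,|E|}{n-1}, \]

with \(N_i\) the degree of mediator \(i\) and \(n\) the total number of
panel mediators analyzed — isolated nodes included, so the score is
comparable across intervals of the same panel. It ranges from 0 (empty)
to \(n\) (complete graph). Degenerate cases are explicit: an interval
with fewer than 3 samples is flagged unevaluable (complexity `NA`), a
zero-variance mediator carries no edges, and a mediator pair with fewer
than 3 pairwise-complete observations is skipped and logged. Samples
enter per-sample, not per-subject-mean; the choice is visible in the
exported summaries.

## Dynamic hypergraph analysis (DyHyp)

DyHyp represents *where* inflammation is rising or falling. Windows are
all runs of 3 consecutive schedule days (`makeWindows`; the 11-day
schedule gives 9 overlapping windows). Within a window, each mediator's
group-mean values are correlated against calendar day per compartment:
r > 0.95 marks it increasing there, r < −0.95 decreasing (strict
comparisons, matching the printed inequalities of the method's
definition). Compartments passing in the same direction form one
hyperedge, so an edge's cardinality (1–3 vertices) measures
cross-compartment spread, and the per-window tally by cardinality and
direction is the edge distribution. Trend detection runs on group
means, not per-animal series, because the emulated design is
cross-sectional (animals contribute a few samples each, and one graph
is drawn per group); a mediator can carry at most one increasing and
one decreasing edge per window, and the two never share a compartment.

Numerical choices worth stating:

- **r-threshold, not p.** With 3 points, |r| > 0.95 still has null
  probability \(1 - (2/\pi)\arctan(0.95/\sqrt{1-0.95^2}) \approx
  0.2022\) (`nullEdgeRateExact`; the formula equals
  \(1-(2/\pi)\arcsin c\) and is independent of the day spacing).
  A nominal p < 0.05 would require |r| > 0.997. The package follows
  the numeric threshold as the operative criterion and surfaces the
  null rate so users can calibrate expectations; edge distributions on
  noisy data sit on this baseline.
- **Calendar day vs index.** Windows crossing the schedule gap
  (d7–d20, d9–d20) are kept and correlated against calendar day by
  default; `timeMode = "index"` ranks the three points instead, for
  sensitivity analysis.
- **Degenerate cells.** A missing or constant (zero-variance) value
  triple yields no trend test; the cell is skipped and logged on the
  graph object.

## The synthetic-data generator

Because the motivating experimental datasets are not publicly
available, the generator is the package's ground truth. It reproduces
the rat design — by default 4–6 named groups of 8 subjects, 3
compartments, the 27-mediator panel and the 11-day schedule — and
plants signals as `TrendSpec`s: linear-in-day ramps between a start and
end day (baseline before, final value held after), increasing or
decreasing, optionally sharing one deterministic trend across several
compartments to express cross-compartment coupling (noise stays
independent per compartment). Linear ramps are the minimal sufficient
signal class: the detector only tests monotone 3-point correlation, so
nothing richer is needed for calibration. `plantedTruth` enumerates,
without simulating, every 3-point window fully inside each trend's
span — the exact hyperedge set a noiseless run must produce.

Noise defaults to multiplicative lognormal with log-sd `sigma = 0.3`
(≈ 30 % CV, a typical between-replicate dispersion for multiplex
immunoassays; concentrations stay strictly positive and right-skewed).
Additive gaussian noise is retained because it makes the no-trend case
exactly the closed-form null model; gaussian draws below zero are
clamped to keep the container's non-negativity invariant (irrelevant at
the default baselines). The paper-scale effect sizes are unknown, so
the bundled `demoSimConfig` slopes (10–40 units/day against baselines
of 100–400) are calibration choices — large enough that noiseless
recovery is exact and 1 %-noise recovery is near-certain — not
estimates of the biology. Random streams are split per
`(group, subject, compartment)` by integer offsets from the master
seed, so appending a group to a config leaves existing groups' draws
byte-identical (prepending or renaming would not).

One geometric caveat, found while validating recovery: a trend whose
span *ends* at the first day after a long schedule gap (day 20 here)
produces a rise-then-hold pattern across the window (11, 20, 23) whose
correlation with calendar day is ≈ 0.97 — above threshold — so such a
spec would yield one hyperedge beyond its `plantedTruth` record under
zero noise. Spans in the bundled scenarios therefore end on 11, 27 or
31 (starting at 20 is safe: the start day sits at baseline). Users
writing their own specs near a schedule gap should expect
partial-window edges of this kind; they are a property of the detector,
not a bug in the generator.

What the generator does *not* emulate: assay floor/ceiling censoring,
between-animal baseline heterogeneity, serial correlation within an
animal, inter-mediator correlation beyond shared trends, and batch
effects. Passing recovery and calibration tests therefore shows the
detectors are correct and calibrated under the stated noise model, not
that they are robust to everything real Luminex data can do.

## Group screens

Concentrations are log-transformed (natural log; zeros get half the
minimum positive value) before testing — the package's choice, as
multiplex data are approximately log-normal and the t/F machinery
assumes roughly symmetric errors. `oneWayTimeAnova` is a standard
one-way F-test across days within a group and compartment.
`twoWayScreen` fits group × day ANOVA per mediator with day as a
categorical factor and samples treated as independent per cell (the
emulated design is cross-sectional; a repeated-measures model would
need within-animal series the design does not provide). The per-day
group comparisons are Holm–Šidák step-down adjusted
(\(1-(1-p_{(i)})^{m-i+1}\), monotonized) within each mediator; the
mediator-level flag follows the group main effect at α = 0.05, and no
across-mediator correction is applied by default (matching how such
significance grids are conventionally reported), with BH optional.
`volcanoScreen` gates on |log2 FC| ≥ 1 (fold change 2) *and* Welch-t
p < 0.05, with fold change computed on the raw concentration scale and
the documented half-minimum substitution when a pooled mean is zero.
Mediators failing preconditions (empty cells, a group absent) are
flagged unevaluable in the output rather than dropped.

## Pipeline and determinism

`runPipeline` drives everything from one YAML/list config: simulate or
load, then any of `crosscorr`, `dyna` (over configurable day-bin
strata, by default schedule quartiles, run per group and compartment),
`dyhyp` and `screen`. Analysis names are validated before any work;
stage errors are recorded in the manifest with earlier artifacts
preserved. All randomness flows from the single seed through the
generator's stream-splitting, so a rerun with the same config is
byte-identical — this is asserted by test, not assumed.

## Problem sizes used by the test suite

The suite verifies oracle equivalence on small instances (≤ 6
variables × 12 observations for Spearman; 4–6 mediators × 5–6 samples
for DyNA; 4 mediators × 3 compartments × 9 windows for the hypergraph
brute force), null calibration with 10^5 Monte-Carlo trend tests and
about 3 × 10^3 simulated no-trend triples, uniformity of 1000 null
ANOVA p-values, planted-trend recovery over 100 seeds at 1 % additive
noise, and end-to-end determinism of the demo pipeline. These sizes
were chosen so that Monte-Carlo standard errors are small relative to
the tolerances being asserted while the whole suite stays quick to run.

## Known limitations

- The census, DyNA and DyHyp are descriptive screens; none of the
  thresholds carries a formal error rate, and the DyHyp null rate of
  ≈ 0.20 per test means single-window edges on noisy data are weak
  evidence by themselves.
- Statistical comparison of complexity curves or edge distributions
  between groups is out of scope; the package computes the summaries,
  not tests on them.
- The screens assume independent samples per cell; designs with true
  repeated measures need a mixed-model treatment the package does not
  provide.
- Wide-format Luminex exports are not parsed; the canonical input is
  the long/tidy CSV dialect.
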