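# immunodyn

Spatiotemporal analysis of inflammatory mediator panels measured across
several tissue compartments — the setting of vascularized composite
allotransplantation (VCA) studies, where cytokines, chemokines and
growth factors are assayed by multiplex immunoassay (Luminex-type
bead sets) in skin, muscle and peripheral blood over a post-transplant
time course. The package is aimed at systems-immunology analysts who
want the dynamic-network toolchain for such data as tested, reusable
functions rather than one-off scripts.

## What it computes

Given a validated long-format table of concentrations keyed by
`{group, subject, compartment, day, mediator}`:

- **Spearman cross-correlation census** (`spearmanCensus`). All
  mediator-at-compartment variables are correlated pairwise (midrank
  Spearman ρ, two-sided p from the t approximation
  t = ρ√((n−2)/(1−ρ²))). `significantCount` and `percentSignificant`
  summarize a panel as *significant pairs / possible pairs*, the usual
  way census heatmaps are compared across experimental groups.
- **Dynamic Network Analysis, DyNA** (`buildDynaNetworks`). For each
  pair of consecutive ordinal strata (severity grades, time bins),
  mediators are joined by an edge when |Pearson r| ≥ 0.90 across the
  pooled samples of the interval. Each network is scored by the
  complexity (N₁ + N₂ + … + Nₙ)/(n − 1) = 2|E|/(n − 1), where Nᵢ is the
  degree of mediator i and n the number of mediators analyzed.
- **Dynamic hypergraph analysis, DyHyp** (`distributionSeries`,
  `buildHypergraph`). Over every sliding window of 3 consecutive
  sampling days, each mediator's group-mean values are correlated
  against calendar day per compartment. Compartments with r > 0.95 form
  the mediator's *increasing* hyperedge, r < −0.95 its *decreasing*
  hyperedge; vertices are the compartments, so an edge spanning 2–3
  vertices is inflammation moving in parallel across tissues. The
  *edge distribution* tallies edges per window by the number of
  compartments spanned and by direction. With 3 points the null
  probability of |r| > c is 1 − (2/π)·arctan(c/√(1−c²)) ≈ 0.202 at
  c = 0.95 (`nullEdgeRateExact`), which is why the numeric cutoff, not
  a nominal p-value, is the operative criterion.
- **Group screens** (`oneWayTimeAnova`, `twoWayScreen`,
  `volcanoScreen`). One-way ANOVA across days, two-way
  (group × day) ANOVA with Holm–Šidák-adjusted per-day comparisons, and
  volcano-style two-group comparison gated at fold change ≥ 2 and
  p < 0.05. Concentrations are log-transformed first.
- **Synthetic studies with known truth** (`simulateMediators`,
  `demoSimConfig`). A generator reproducing the rat hind-limb design
  (4 groups × 8 animals, 27-mediator panel, days
  0,3,5,7,9,11,20,23,25,27,31) with planted linear trends, lognormal or
  gaussian noise, and a `plantedTruth` record for recovery testing.
- **One-config pipeline** (`runPipeline`): simulate/load → census →
  DyNA → DyHyp → screens, deterministic under a seed, every artifact
  listed in a JSON manifest. `inst/scripts/run_pipeline.R` is a thin
  shell wrapper.

## Worked example

```r
library(immunodyn)

sim <- simulateMediators(demoSimConfig(seed = 42))
ser <- distributionSeries(sim$experiment, "allo_TAC_NR")
ser$graphs[[8]]
#> DyHypGraph window (23, 25, 27), |r| > 0.95
#>   vertices: skin, muscle, blood
#>   edges: 20 (11 increasing, 9 decreasing)

res <- spearmanCensus(sim$experiment, groups = "allo_TAC_NR")
res
#> CorrResult: 81 variables, 3240 unordered pairs
#>   significant at 0.05: 209 (6.5%)

nullEdgeRateExact(0.95)
#> [1] 0.2021652
```

The demo scenario plants, among others, an IP-10 trend spanning all
three compartments and an IL-17A trend spanning muscle and blood late
after allogeneic transplant with nerve repair; at `sigma = 0` the
hypergraph series recovers exactly those hyperedges and nothing else.
The 20 edges above are the planted trends plus the noise-induced edges
expected at the ≈ 0.202 per-test null rate under the default
`sigma = 0.3` lognormal noise. The census percentage (6.5 %) sits just
above the 5 % nominal null level because planted trends induce genuine
co-movement.

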