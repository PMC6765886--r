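---
title: "Modelling the health impact of prohibiting characterizing flavors in cigars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the health impact of prohibiting characterizing flavors in cigars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavorsim)
```

## The policy question and the two model chains

Several US localities restrict the sale of flavored tobacco products, including
cigars; flavored cigars account for roughly half of US cigar sales and most
young cigar users initiate with a flavored product. `flavorsim` models the
health impact of extending such a prohibition nationwide, through two static,
single-cohort chains of multiplications.

**Cessation-mortality chain.** Among the attributable premature deaths per year
from exclusive regular cigar smoking (default 5200/year; dual users of
cigarettes and cigars are excluded because they may switch products rather than
quit), a flavor prohibition reduces total cigar consumption by an uncertain
proportion `R`, and an uncertain fraction `Q` of that reduction is complete
cessation. Only complete cessation earns a mortality benefit:

$$\text{deaths avoided/year} = A \times R \times Q .$$

Cigar-use prevalence is assumed stable absent the policy, so the output is a
steady-state annual rate, not a projection over calendar time. At the modal
inputs (R = 30%, Q = 50%) this is 5200 × 0.30 × 0.50 = 780.

**Initiation/continuation chain.** In one cohort of 18 year olds (default 4.2
million), a proportion `p` are current cigar users (default 7.2%,
every-day/some-day use) and a fraction `f` of those initiated with a flavored
cigar (default 65.4%), giving a flavored-initiate base `N·p·f` (197,769.6
persons, unrounded). Removing flavors deters an uncertain proportion `D` of
that base from initiating at all, and among the `1 − D` who still initiate,
reduces continuing use by an uncertain proportion `C`:

$$\text{users prevented} = N p f \,\bigl[D + (1 - D)\,C\bigr].$$

`C`'s most likely value is derived from the adjusted prevalence ratio `PR` of
current regular use among flavored vs non-flavored initiates as `1 − 1/PR`
(1 − 1/1.56 = 35.9%), with its bounds taken from the ratio's 95% confidence
interval (1.29, 1.87 → 22.5%, 46.5%). The scenario constructor checks, to three
decimals, that the configured mode equals `1 − 1/PR`, but never silently
re-derives the bounds. Dividing total users prevented by the cohort's current
users (`N·p`) gives the relative prevalence reduction.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `attributable_deaths` | 5200 | deaths/year | exclusive regular (15+ of past 30 days) cigar smokers only |
| `consumption_reduction` | Tri(0.15, 0.30, 0.45) | proportion | observed sales declines after local flavor restrictions; upper bound ≈ flavored market share |
| `cessation_fraction` | Tri(0.25, 0.50, 0.75) | proportion | about half of sales reductions after tax increases come from quitting entirely |
| `cohort_size` | 4,200,000 | persons | US 18-year-old cohort, 2016 |
| `current_use_prevalence` | 0.072 | proportion | every-day/some-day use at 18; a past-30-day alternative (0.131) is a supported scenario, not the default |
| `flavored_initiation_fraction` | 0.654 | proportion | current users whose first cigar was flavored |
| `initiation_reduction` | Tri(0, 0.325, 0.65) | proportion | midpoint of "no deterrence" and "all deterred minus current non-flavored initiation" |
| `continuing_prevalence_ratio` | 1.56 | ratio | adjusted PR of continued regular use, flavored vs non-flavored initiates |
| `continuing_reduction` | Tri(0.225, 0.359, 0.465) | proportion | 1 − 1/PR at the PR's point estimate and CI bounds |
| `n_iterations` | 1000 | count | the published run size; increase (1e5+) for stable interval bounds |
| `interval_mass` | 0.90 | probability | central prediction-interval mass |

The machine-made share (92%) and flavored retail share (52.1%) are carried on
the mortality scenario because their product (47.9%) is the stated rationale
for the 45% consumption-reduction upper bound. We keep the configured bound at
the tabulated 45% rather than the exact product — the source analysis rounds
the product down and the bound is an input in its own right —
`flavored_market_share_bound()` reports the exact product so the gap is
visible.

## Uncertainty propagation and numerical choices

Every uncertain input is a **triangular distribution** (min, mode, max) — the
standard encoding of expert bounds plus a best estimate in this literature.
Sampling is by **inverse-CDF transform** of a single uniform stream
(`tri_ppf` applied to `runif`), chosen over rejection sampling so that a run is
reproducible from one integer seed and each iteration's draw maps one-to-one to
a uniform variate. Degenerate (point-mass) distributions are legal, so
deterministic and stochastic runs share one code path and a degenerate scenario
collapses the prediction interval onto the point estimate.

Inputs are sampled **independently**: no correlation structure is asserted
between, say, how much consumption falls and how much of that fall is
cessation. The independence is what makes the closed-form expectations used
throughout the tests valid, e.g.
`E[D + (1 − D)C] = E[D] + (1 − E[D])E[C]`; a future correlated extension must
revisit every such factorization (they are all confined to
`analytic_expectation()` and the test oracles).

The **prediction interval** is the pair of empirical quantiles at
`(1 ± interval_mass)/2`, computed by linear interpolation on the order
statistics (minimum at q = 0, maximum at q = 1). At 1000 iterations the choice
of quantile estimator moves the bounds by less than Monte Carlo noise. Full
precision is carried through every chain; rounding (persons to the nearest
1,000, deaths to the nearest death, percentages to one decimal) happens only in
the report layer. This matters: the published 37.1% prevalence reduction is
reproduced by the unrounded chain (0.37104) but not by rounded intermediates
(0.3704).

```{r}
res <- run_simulation(mortality_scenario(), sim_settings(1e5, seed = 7))
res
```

## One-way sensitivity: the reconstruction decision

The published one-way ranges for the mortality model (522–1057 and 509–1055
deaths avoided) are far narrower than min/max substitution gives (390–1170 for
both inputs, coincidentally identical because the two triples have symmetric
corner products). They are, however, closely matched by **conditional output
means over the outer deciles** of each input's Monte Carlo draws: for the
product model, `E[output | X in outer decile] = A · E[X | decile] · E[Y]`,
which at the default inputs gives ≈506 and ≈1054. We therefore implement the
tornado as decile-conditional means (`conditional_mean_range()`, `n_bins`
configurable, iterations are ranked and split into equal-count bins), and
always report plain one-at-a-time substitution (`one_at_a_time()`) alongside it
so the reconstruction's assumptions are visible. The exact procedure behind the
published ranges (bin count; means vs percentiles of the conditioned output) is
not documented in the source analysis, so agreement is expected only within
Monte Carlo tolerance; the closed-form decile expectations
(`tri_bin_mean()`) provide the analytic anchor the implementation is tested
against.

```{r}
tornado(res, n_bins = 10)
```

## What the synthetic generator emulates — and what it does not

`generate_scenarios()` draws random, structurally valid scenarios of both kinds
(sorted uniform triples for the distributions; the continuing-use reduction
built consistently from a random prevalence ratio) and pairs each with its
closed-form expected output. This gives the test suite a parameter-recovery
surface: the engine's mean must match the paired expectation within CLT bounds
across the whole family, not just at the published inputs.

The generator emulates the *structure* of the analysis (point inputs plus
triangular uncertainty, multiplicative chains), not real-world data: it does
not simulate survey microdata, correlated inputs, behavioral feedback,
substitution toward other tobacco products, multi-year dynamics, or morbidity.
Passing tests therefore demonstrate that the arithmetic, sampling and
summarization are correct under the model's assumptions — not that the model's
inputs are externally valid.

## Problem sizes and reproducibility

The packaged analyses run the published 1000-iteration size for the headline
tables and 100,000–200,000 iterations where stable interval bounds are wanted
(the tests and the acceptance script use these larger sizes; a 200,000-iteration
run of either model takes well under a second). Every simulation is seeded
through `sim_settings(seed = ...)`; reruns with the same seed are bit-identical,
and the engine restores the caller's RNG state afterwards.

## Known limitations

- Static single-cohort, single-year model: no accumulation of benefits across
  successive cohorts, no lag between cessation and mortality benefit, no
  life-years metric.
- The initiation model's published simulation mean (108,846) sits about 2%
  below the analytic expectation of the stated inputs (≈110,950); the package
  reproduces the analytic value, and comparisons against the published
  simulation numbers must carry that gap as tolerance context. Likewise the
  published 5th percentile (75,914) sits about 5% below the large-sample value
  of the stated input distributions (≈79,760) — consistent with a single
  1000-iteration run.
- No mortality benefit is assigned to cutting back without quitting, and
  morbidity benefits are out of scope; in those respects the estimates are
  conservative by construction.
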