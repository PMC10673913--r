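---
title: "Co-consumption networks: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-consumption networks: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccnet)
```

This vignette is the package's account of its own methodology: what the
co-consumption network (CCN) estimator assumes, which knobs matter, what
the synthetic cohort generator does and does not emulate, and where the
design was genuinely open and a choice had to be made.

## The estimator

The data are a matrix of usual intake in grams per day, participants by
food groups, typically derived from a food frequency questionnaire. The CCN
treats "co-consumption" as a population property of a pair of food groups:
a monotone association between their intakes across people. Spearman rank
correlation is used throughout because intake distributions are heavily
right-skewed and zero-inflated; rank methods are invariant to the monotone
transformations (portion-size conversions, unit changes) these data go
through.

A naive correlation network at a fixed threshold would inherit the sampling
noise of a single sample. The CCN instead requires *stability under
resampling*: participants are split at random into a test and a validation
half, `n_repeats = 100` times, and a pair is connected only if

1. its correlation is significant at `alpha = 0.05` in **both** halves of
   **every** repeat,
2. it is positive in both halves of every repeat, and
3. the mean of the 100 test-half coefficients exceeds the soft threshold
   `r_threshold = 0.2`.

The conjunction over 200 tests is a severe multiplicity control in itself:
under independence the chance that a null pair survives is bounded by
`alpha^200`, which is why no explicit p-value correction across the
`choose(40, 2) = 780` pairs is applied. One failing repeat kills an edge —
the strict reading of "all repeats"; with a true correlation near the
detection boundary this makes edges conservative rather than liberal.

Node weight is the *consumption score*: the number of participants whose
intake of the group strictly exceeds the group's first quartile. The strict
inequality matters: for a tie-free column of *n* participants it labels
roughly 75% of them consumers (exactly `0.75 n` when `0.25 (n - 1)` is an
integer — for `n = 1500`, a score of 1125), and for a zero-inflated column
whose first quartile is zero it labels exactly the non-zero consumers. A
non-strict rule would label *everyone* a consumer of a tie-free group,
which is useless as a node weight. Quantiles use linear interpolation
between order statistics (`type = 7`, the R default); the convention is
configurable because the choice is not identified by theory.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `n_repeats` | 100 | splits | stability requirement of the edge filter |
| `split_fraction` | 0.5 | — | equal halves; no ratio is canonical, configurable |
| `alpha` | 0.05 | — | per-test two-sided level inside the filter |
| `r_threshold` | 0.2 | Spearman rho | soft threshold separating "weak but real" from "co-consumed" |
| `n_runs` | 50 | restarts | consensus over label-propagation randomness |
| `p_threshold` | 0.1 | probability | hypergeometric membership criterion |
| `age_cutoffs` | 30, 50 | years | young / middle / old strata |
| `cap_cutoffs` | 238, 260, 293 | dB/m | steatosis grades S0–S3; first and last also define the normal/NAFLD strata |
| `min_clique` | 4 | nodes | smallest clique worth a module-association test |
| `fdr_level` | 0.05 | — | Benjamini–Hochberg cutoff for "related" cliques |

## Communities, membership, contrasts

Label propagation is a topological algorithm: nodes repeatedly adopt the
modal label of their neighbors, ties broken at random, until every label is
modal in its neighborhood. Its stochasticity is handled by consensus: 50
restarts, each partition canonicalized (module ids renumbered along the
sorted node names), and the most frequent canonical form kept. Frequency
ties are broken by higher modularity, then by lexicographically smallest
canonical form — an arbitrary but deterministic last resort. Modularity is
computed on the unweighted topology as `Q = sum_c (e_cc - a_c^2)`.
Isolated nodes belong to no module.

Participant membership uses a hypergeometric over-representation test. The
framing had to be chosen (the quantities are not forced by the method's
one-line description): the population is the `N` module-labeled food groups
(isolated nodes excluded), a participant "draws" the `n` labeled groups
they consume, and `k` of those fall in the candidate module of size `K`;
the upper tail `P(X >= k)` measures enrichment. This is the only framing in
which "member of both modules" and "member of neither" are both possible,
which the three-label output (unhealthy / healthy / other) requires. A
participant consuming nothing has `p = 1` for both modules. Whether the
population should instead include isolated groups is unresolved; `N` =
labeled groups is the default and the matrix passed in is under the
caller's control.

The two modules are named by outcome: the one whose members carry the
higher mean CAP score is "unhealthy". Member contrasts use the pooled
two-sample t-test (a Welch variant is available via `var_equal = FALSE`)
and chi-square tests for sex and the steatosis-grade distribution. CAP
grade boundaries are left-closed except S0: a CAP of exactly 238 dB/m is
S1 and exactly 293 dB/m is S3, matching the strict "< 238 is normal" and
">= 293 is NAFLD" stratification rules used for the disease networks.

Differential networks are tagged symmetric differences of two stratum
networks built with identical settings; every edge carries exactly one
origin tag and weight 1. The age-trend network keeps a pair when it is
significantly positively correlated in the oldest stratum (eligibility is
configurable to "any" or "all" strata) and its per-stratum coefficients
either increase strictly across the three strata or rise by more than 0.25
from youngest to oldest. Per-stratum trend coefficients use the full
stratum sample, not split halves: the trend definition compares single
per-stratum coefficients, and the 100-repeat machinery is an edge filter,
not an estimator of a correlation difference. Strict three-stratum
monotonicity is the default reading of "increasing across the age
categories"; the weaker old-greater-than-young reading is available via
`strict = FALSE`.

Clique association uses Pearson's chi-square on the 2×2 table
(consumes-all-groups vs not × unhealthy member vs healthy member)
**without** Yates continuity correction — the corrected statistic no longer
equals the closed form `n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` that the
percentages-from-counts arithmetic checks rely on, and published tables of
this kind include cells small enough that the correction would change
calls. Tables with an expected cell below 5 are flagged (`low_expected`)
rather than suppressed.

## The synthetic cohort generator

`simulate_cohort()` draws cohorts with the statistical structure the CCN
analysis assumes, so recovery can be scored against ground truth. Each
participant has latent adherences `(H, U)` to the healthy and unhealthy
patterns — bivariate standard normal with correlation `rho_hu = 0.15`, `U`
shifted by standardized age (0.3 per SD) and a centered female indicator
(0.5) — and intake `X = B * exp(mu + lambda * A + sigma * eps)` with an
independent Bernoulli zero-inflation mask `B`. CAP is
`235 + 20 U - 15 H + N(0, 40)` dB/m, clamped to the physically plausible
100–400 range; energy and BMI also rise with `U`.

The default specification fixes the study conditions once: 1500
participants, 62% female, age normal(40.9, 11.6) truncated to the 20–60
eligibility window, and 40 food groups of which 20 load on the unhealthy
block, 18 on the healthy block and 2 are neutral (so they surface as the
two isolated nodes). Per-group locations come from published median
intakes, zero-inflation rates from published consumer counts, and loadings
scale with published node degrees (`lambda = 0.4 + 0.055 * degree`, capped
at 0.95) — hubs load harder, so the planted networks are star-ish rather
than uniform cliques, and the implied pairwise population Spearman
correlations span roughly 0.1–0.5, the range such intake networks report.

The ground-truth record is *population-level*: for every within- and
cross-block pair it stores the latent Gaussian correlation and the exact
population Spearman correlation under zero inflation, computed in closed
form from the Gaussian grade correlation `(6/pi) asin(r/2)` extended with
the zero atom (the mid-rank grade correlation of the mixture; see
`population_spearman()`, which is itself tested against Monte-Carlo
grades). "Planted edges" are the within-block pairs whose population
Spearman reaches 0.3 — comfortably above the 0.2 soft threshold, so their
recovery is a property of the estimator, not of sampling luck.

What the generator does **not** emulate: nutrient composition and
energy-adjustment artifacts, seasonal or longitudinal diet change,
measurement error structure of FFQ instruments (systematic over-reporting,
item-specific recall bias), and negative co-consumption (substitution). A
passing recovery suite therefore shows the pipeline correctly recovers the
modeled structure — shared multiplicative factors under zero inflation —
not that real FFQ data satisfy that model. An optional `sex_pair` component
plants a single stratum-exclusive co-consumption (a shared factor active in
one sex only) to exercise the differential-network machinery; it is off by
default so the neutral groups stay isolated.

## Numerical conventions and degenerate inputs

* Spearman p-values use the t approximation on `n - 2` degrees of freedom
  (the standard large-sample treatment with ties); `|rho| = 1` maps to
  `p = 0`.
* A column constant within a split half has undefined correlation; such a
  repeat counts as non-significant, so the pair cannot become an edge.
  All-zero intake columns binarize to all zeros (score 0) without error.
* Split indices are drawn after sorting rows by participant ID, making
  `validate_edges` invariant to input row order at fixed seed.
* All pipeline randomness derives from one global seed through per-stage
  seeds (a hash of the stage name), so stages are independently
  reproducible; functions restore the caller's RNG state.
* Missing intake values are rejected, never imputed: the intended input is
  a completely administered FFQ, and silent imputation would distort ranks.

## Problem sizes in the test suite

The suite checks oracle equivalence (modularity, centralities, cliques,
hypergeometric tails) on exhaustively enumerable graphs of up to 12 nodes;
null/perfect edge behavior and full ground-truth recovery on the default
1500 × 40 cohort over 20 generator seeds; and pipeline consistency on a
600-participant cohort. These sizes make the whole suite run in a few
minutes on one core while keeping every probabilistic margin wide (the
recovery checks pass with headroom, not at the boundary).

## Known limitations

* Only positive correlations form edges; substitution patterns (negative
  co-consumption) are invisible by design.
* Marginal correlation networks conflate direct and indirect association;
  a Gaussian graphical model would give a sparser, partial-correlation
  view — deliberately out of scope here.
* Membership is a per-participant enrichment call at a fixed threshold,
  not a probabilistic mixed-membership model; the "other" group mixes
  truly intermediate diets with low-information participants.
* The consensus partition is the modal answer of a stochastic algorithm;
  on graphs with genuinely ambiguous community structure the modal answer
  can itself be unstable between seeds (the `frequency` attribute exposes
  this).
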