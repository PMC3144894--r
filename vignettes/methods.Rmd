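---
title: "From daily observations to longevity: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From daily observations to longevity: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(socnetlong)
```

This vignette documents the statistical machinery in `socnetlong`, the
assumptions behind each stage, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
design choices made where the methodology left genuine latitude.

## The data model

The raw material is a long-format table of daily focal observations — one
row per individual per interaction event, with the event's type
(`affiliative_contact`, `coordinated_activity`, `agonistic`,
`tree_foraging`) and a marked flag — plus per-individual capture metadata
and multi-year encounter histories. Individuals not captured as pups are
aged from body weight with sex-specific log-log calibration curves
(`hyrax_age_models()`); because rock hyraxes breed synchronously in early
spring, pups are aged from March 1 of the capture year and yearling
juveniles from March 1 of the previous year. Age classes are pups (≤ 1
year), juveniles (1–2 years, exclusive) and adults (≥ 2 years). The log
base (10) and age unit (days) of the calibration are configurable in
`age_model()`: they are not identifiable from the printed coefficients
alone, and base 10 with days is the only combination that puts 3–4 kg
adults at plausible ages of a few years.

## Association networks

Durations of wild social interactions are hard to measure when up to ten
animals are followed at once, so presence/absence at **one-day
resolution** equalizes observation effort: a dyad is "together" on a day
if it co-occurs in at least one retained positive interaction event that
day. Tree-foraging records are excluded (tree crowns force proximity
without social context), agonistic records are excluded (they are not
positive associations — they feed the aggression covariates instead), and
any event containing an unmarked animal is dropped whole, since unmarked
animals cannot be identified across days.

The simple ratio index is `x / (d_i + d_j − b)`: days together over the
union of sighting days. Note `b` counts days both were *seen* — two
animals can be recorded on the same day in different events, which
enlarges the union relative to days-together alone. A configurable
alternative reading ("together = co-membership in ≥ 1 event",
which this package uses) versus same-scan co-sighting is exposed through
how events are built upstream; the package deliberately counts event
co-membership because interaction records, not mere co-sightings, are the
unit of the field protocol.

Individuals seen on zero days in a period have no defined index and are
dropped from that period's network.

## The permutation gate

Random aggregation produces apparent associations, so each network must
first show more dyadic structure than chance. The null model preserves
two things exactly: every individual's set of sighting days, and the size
of every interaction cluster on every day. A *checkerboard swap* exchanges
two individuals between two clusters of the same day; a long Markov chain
of such swaps explores the constrained null space. Within-day swapping is
the default (a switch the user controls by how periods are built), the
conservative choice when daily presence varies.

The test statistic is the **SD of all dyadic association indices**:
preferred long-term companionship concentrates association in particular
dyads and inflates the SD (upper tail); avoidance deflates it (lower tail
option). The coefficient of variation and the mean are available
alternatives. The p-value uses the add-one rule `(b + 1)/(n + 1)`, so it
can never be exactly zero.

Defaults: 1,000 burn-in swaps, 100 swaps between retained permutations,
up to 10,000 permutations accumulated in blocks of 1,000, stopping early
when p changes by less than 0.01 between consecutive blocks ("p-value
stabilized"; set the tolerance to 0 to force the full run). Calibration
was checked by simulation: on structureless fixtures the rejection rate
at α = 0.05 is consistent with 5% and the p distribution is uniform
(Kolmogorov–Smirnov); on fixtures with two persistent cliques, p ≤ 0.01
essentially always. Networks with p ≥ α are excluded from all downstream
stages, with a log message.

## Weighted clique percolation (CPMw)

Groups are not imposed; they are read off the network. A k-clique's
*intensity* is the geometric mean of its edge weights; cliques with
intensity at or above a threshold are chained whenever they share k − 1
members, and each chained component's node union is a community.
Communities may overlap; animals covered by no retained clique are
*solitary*. Defaults: k = 3 (the smallest meaningful clique and the usual
default of percolation software; the original analysis did not report
its k).

The intensity threshold is data-dependent. `select_threshold()` scans the
distinct clique intensities (bisection over at most 25 candidates) and
returns the largest threshold at which the giant community still covers
at least half of the clique-covered nodes — just below the percolation
critical point, where communities are as strongly knit as possible
without the network shattering. This matters in practice: at threshold 0,
rare weak between-group edges form bridging triangles that merge two
resident groups of the same site into one block.

Downstream group statistics need disjoint groups, so an animal in
several communities is assigned to the one where its within-community
strength is largest (ties: the larger community, then lexicographic). The
overlapping assignment is preserved in the result object.

## The seven network measures

Per individual: **strength** (row sum of association weights), **Bonacich
power** `c = (I − βW)⁻¹W·1` (β defaults to half the reciprocal spectral
radius — well inside the convergence bound, and recorded in the output
since the original β is unreported), and **information centrality** from
`C = (D − W + J)⁻¹`, with weights treated as conductances. Per group: the
population SD of each individual measure within the group — the group
*inequality* measures that carry the main biological signal — plus
distance-based **cohesion** (mean inverse shortest-path distance; edge
length defaults to 1/w, with a binary option) and **centralization**
`Σ(s_max − s_i) / ((n−1)(n−2) w_max)`. There is no standard weighted
centralization normalization; this w_max-scaled Freeman form is chosen so
the anchors hold exactly (uniform star = 1, weight-regular = 0) and is
documented prominently because absolute values depend on it. Population
(divide-by-n) SD is the default because that is the convention of the
network software this field uses; the sample estimator is an option.

Information centrality requires a connected graph and is computed on each
group's subnetwork; a disconnected subnetwork yields NA rather than a
silently wrong number.

## Longevity analysis

Only individuals of known age that died as adults enter the panel; each
metric is the arithmetic mean over the animal's adult years (ages two to
death), with missing years dropped (warned). Age at death is regressed on
each averaged metric by OLS. Because age at death is skewed,
**randomization p-values** are used: the response is permuted (default
10,000 times; two-tailed on the slope, since the original direction of
testing is unreported), and the add-one rule applied. Group size is
removed by **residual control** (OLS residuals of age on group size),
which by Frisch–Waugh–Lovell reproduces the partial slope of the joint
regression; both raw and controlled fits are reported for every metric,
and no multiple-testing correction is applied across the seven metrics
(matching the original reporting; the count of tests is visible in the
report). Dependency between group-mates is checked by a **fixed-effects
group model**: OLS with a group indicator block plus the predictor, with
partial F tests for each term. This reproduces the reported F-test
structure (e.g. F with 5 and 27 df for six groups and n = 34) without a
mixed-model dependency; it is an approximation of a random-effect
formulation and is labelled as such. Aggression enters as residual rates:
agonistic-day counts adjusted by OLS for group size and observation days.

## The Barker survival model

Seven parameters per interval: survival S, capture p (given at risk),
dead recovery r, resight R (given survival), resight-before-death R′,
fidelity F, re-immigration F′. The likelihood is a per-animal forward
recursion over hidden states {alive at risk, alive off risk, dead
unobserved}, conditioned on first release: each interval applies
survival, the resight/recovery emission (R on the survival branch, R′
then r on the death branch), the fidelity transition, and the capture
emission at the next occasion (off-risk animals cannot be captured). This
formulation is algebraically equivalent to the classical multinomial
form and — the point of choosing it — is mechanically verifiable: the
tests compare it to exhaustive hidden-path enumeration at T ≤ 4 (1e-12)
and check that probabilities over all possible histories sum to one.
With r = R = R′ = 0 and F = 1 it collapses to CJS, which the tests
confirm against an independent CJS implementation.

Structures are formulas per parameter over animal covariates and `time`
(`~1`, `~group`, `~time`, additive combinations) on the logit link, with
fixed values supported (e.g. F′ = 0 for permanent emigration).
Optimization is BFGS (relative tolerance 1e-12, optional jittered
multi-start with a fixed seed); non-convergence and near-boundary
coefficients (|logit| > 8) are flagged, never silent. Standard errors
come from the numerical information matrix, real-scale estimates by the
delta method. Model selection uses QAICc
`= −2lnL/ĉ + 2K + 2K(K+1)/(n_eff − K − 1)` with Akaike weights;
overdispersion ĉ is a user input (externally estimated; reproducing the
median-ĉ bootstrap is out of scope), and the effective sample size is
the number of released animals — conventions differ by data type, so
this choice is stated rather than hidden. Model averaging combines
estimates with the usual unconditional SE; terminal-occasion confounding
is a known limitation of any such model and shows up as inflated SEs
rather than being masked.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
with two sites of two groups each by default. Each individual gets a
lognormal *gregariousness* multiplier with unit mean; a pair's daily
interaction propensity is the within- or between-group base rate times
both multipliers (clamped to [0, 1]). The multiplicative form is the
simplest mechanism that spreads centrality within a group without moving
the group's mean association much — a modelling convenience, not a claim
about hyrax behaviour. The log-scale SD (*heterogeneity*) is the knob
that controls the expected within-group centrality SD, and the default
varies across groups (0.1/0.25/0.4/0.55) so that group-level inequality
actually varies between groups. Observation sampling: 30 days per yearly
season (the scale of one field season), daily presence with probability
0.85, realized pairwise interactions emitted as two-animal events, with
optional agonistic/tree-foraging/unmarked contamination to exercise the
filters.

Longevity is discrete yearly survival from age two: the death probability
each adult year is logistic in the standardized group centrality SD and
group size measured from the simulated networks that year
(`plogis(qlogis(0.3) + 1.4·z_SD + 0.5·z_size)` by default). The positive
hazard coefficients produce the negative longevity slopes the analysis
should recover; their size was fixed a priori so that the effect is
clearly detectable (r² around 0.3) at the study's panel size of 34 dead
adults, a regime consistent with field studies of this kind. The
end-to-end study simulator treats every panel animal as entering
adulthood in the first period, keeps group membership fixed across years,
censors animals alive at study end, and caps the panel at the first 34
dead adults. The permutation gate is skipped inside the study simulator
(its calibration and power are validated separately): the generator
builds association structure by construction.

What the generator does **not** emulate: dispersal and demographic
turnover between groups, seasonal variation in observation effort,
spatial structure within sites, age-dependent sociality, and
individually varying detection. Passing tests therefore show that the
pipeline recovers effects from data with the assumed structure — not
that real field data satisfy those assumptions.

Encounter histories are simulated by the exact generative process the
likelihood describes (the simulator and likelihood were written as
separate codepaths, and the tests check them against each other), with
optional staggered entry and per-animal (e.g. group-dependent)
parameters.

## Numerical choices and degenerate inputs

* Add-one permutation p-values everywhere; p = 0 is impossible.
* The association index is an error, not 0, when neither animal was ever
  seen; consistency violations (together-days outside either animal's
  sighting days, cliques with missing edges, events after a dead
  recovery) raise typed errors.
* Swap chains flag a no-op when no day has two clusters; the permutation
  test refuses degenerate structures (< 2 individuals or days).
* `bonacich_power()` refuses β at or beyond 1/ρ(W) and names the bound.
* Problem sizes in the shipped tests (e.g. 200 calibration replicates,
  100 study replicates, 2,000 animals × 8 occasions for parameter
  recovery, 50 survival-contrast replicates) are the package's chosen
  simulation scales: large enough for the binomial/Monte-Carlo tolerances
  asserted, small enough to run routinely.

## Known limitations

* Group labels are period-local (`G1`, `G2`, ... per network); tracking a
  group's identity across years is left to the user, as in the original
  workflow where it is a judgment call.
* The fixed-effects group term is not a true random effect; with many
  small groups it spends degrees of freedom liberally.
* The weighted centralization normalization is package-defined (see
  above); compare only values computed by the same rule.
* QAICc's effective-n and MARK's internal conventions differ across data
  types; QAICc differences within a model set fitted by this package are
  consistent, but absolute values need not match other software
  digit-for-digit.
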