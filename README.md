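# socnetlong

Social association networks, group structure, and longevity in wild
group-living mammals.

Long-term field studies of marked, plural-breeding mammals (the motivating
system is the rock hyrax, *Procavia capensis*) record daily focal
observations of who interacts with whom, plus multi-year
capture–resight–recovery histories. `socnetlong` turns those records into
the full analysis chain linking social structure to adult longevity and
survival:

1. **Association networks** — at one-day resolution, the simple-ratio
   association index for a dyad is

   `SRI_ij = x_ij / (d_i + d_j − b_ij)`

   where `x_ij` is the number of days the pair was recorded in a positive
   interaction together, `d_i`, `d_j` the days each was recorded and
   `b_ij` the days both were recorded (so the denominator is the union of
   their sighting days). Tree-foraging and agonistic records and any event
   containing unmarked animals are excluded first.
2. **Nonrandomness gate** — a Bejder-style within-sample permutation test:
   a Markov chain of checkerboard swaps exchanges individuals between
   interaction clusters of the same day, preserving cluster sizes and
   individual sighting records, and the SD of the dyadic indices is
   compared to this constrained null (upper tail = preferred long-term
   companionship). Only networks with p < α enter further analysis.
3. **Social groups** — weighted clique percolation (CPMw): k-cliques whose
   edge-weight geometric mean (*intensity*) clears a threshold are chained
   whenever they share k−1 members; chained cliques form communities,
   uncovered animals are *solitary*.
4. **Centrality** — per individual: strength `s_i = Σ_j w_ij`, Bonacich
   power `c = (I − βW)⁻¹W·1`, and Stephenson–Zelen information centrality
   from `C = (D − W + J)⁻¹`. Per group: the SD of each individual measure
   (the group inequality measures), distance-based cohesion
   (mean inverse shortest-path length), and Freeman-style centralization
   normalized by the maximum edge weight.
5. **Longevity regressions** — each metric is averaged over an
   individual's adult years (age two to death), regressed on age at death
   by OLS, with Manly randomization p-values (the response is permuted and
   the slope refit), residual control for group size, a fixed-effects
   group term to check group-mate dependency, and aggression rates as
   residual-adjusted covariates.
6. **Survival** — a Barker joint live-recapture / dead-recovery /
   live-resight model (parameters S, p, r, R, R′, F, F′) implemented as a
   hidden-state forward recursion, fitted by maximum likelihood on the
   logit scale, with QAICc model selection, Akaike weights, model
   averaging and likelihood-ratio tests — e.g. to contrast solitary-male
   vs group-member survival.

A synthetic-data generator (`simulate_population()`,
`simulate_observations()`, `simulate_longevity()`,
`simulate_encounter_histories()`, `simulate_study()`) emulates the whole
observation process with known ground truth, so every stage is testable
without field data.

## Worked example

```r
library(socnetlong)

pop <- simulate_population(population_config(), seed = 2)
obs <- simulate_observations(pop, seed = 2)
f   <- filter_records(obs)                      # positive, marked-only events
am  <- association_matrix(f[f$site == "A", ], period = "2001", site = "A")
am[1:4, 1:4]
#>            ind001     ind002     ind003     ind004
#> ind001 0.00000000 0.07142857 0.20000000 0.07142857
#> ind002 0.07142857 0.00000000 0.33333333 0.17241379
#> ind003 0.20000000 0.33333333 0.00000000 0.06896552
#> ind004 0.07142857 0.17241379 0.06896552 0.00000000
```

Entry (i, j) is the fraction of observation days the pair spent together;
e.g. ind002 and ind003 co-occurred on a third of the days either was seen.

```r
set.seed(2)
pt <- permutation_test(sampling_structure(f[f$site == "A", ]),
                       max_perm = 500, stabilization_tol = 0)
pt
#> <perm_test> stat=sd observed=0.1395 p=0.001996 (500 permutations, upper tail)
```

The observed dispersion of indices exceeds every constrained shuffle:
these animals have preferred companions, so the network is kept.

```r
comm <- cpmw_communities(am, k = 3, intensity_threshold = select_threshold(am))
comm
#> <cpmw_communities> k=3, intensity >= 0.245: 2 communities, 1 solitary
glance(centrality_table(am, comm))
#> # A tibble: 2 × 7
#>   community     n sd_strength sd_power sd_information cohesion centralization
#> 1 G1           13       0.367    0.666         0.0956    0.203          0.128
#> 2 G2           12       0.769    1.51          0.212     0.243          0.190
```

Clique percolation recovers the two resident groups (plus one solitary
animal); G2 is the more unequal group (higher strength-centrality SD).

```r
study <- simulate_study(seed = 1, n_perm = 999)   # full multi-year study
dplyr::filter(study$regressions,
              metric %in% c("sd_strength", "group_size"), !controlled)
#> # A tibble: 2 × 6
#>   metric      controlled  slope r_squared p_value     n
#> 1 sd_strength FALSE      -9.87      0.392   0.001    34
#> 2 group_size  FALSE      -0.757     0.257   0.001    34
```

Across a panel of 34 simulated dead adults, longevity declines with the
within-group centrality SD (and with group size) — the randomization p is
the fraction of response permutations with at least as extreme a slope.

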