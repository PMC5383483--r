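# sexlability

Analysis of labile sex expression in longitudinal plant censuses.

Subdioecious plants — populations of mostly separate males and females with
a minority of hermaphrodites — can change the sex they express from one
flowering season to the next. Given a yearly census that records each tagged
individual as one of six sexual categories (female `F`, male `M`,
hermaphrodite `H`, and mixed hermaphrodites `HF`, `HM`, `HFM`), plus
non-flowering (`NF`) and unobserved (`NA`) years, this package answers the
three standard questions about such a population:

* **Patterns** — each individual's trajectory is reduced to a canonical
  change pattern (`A`, `A→B`, `A→B→A`, ...) and classified as constant,
  unidirectional or bidirectional (`canonicalize()`,
  `tabulate_patterns()`).
* **Long-run sex ratio** — year-to-year transitions define a discrete-time
  Markov chain; the stationary distribution π (with πP = π) is the long-run
  expected female : male : hermaphrodite ratio if transition probabilities
  stay constant. Bootstrap resampling of the transition events gives
  percentile confidence intervals and a test against the uniform
  1/3 : 1/3 : 1/3 null (`count_transitions()`, `to_probabilities()`,
  `stationary()`, `steady_state_test()`).
* **Correlates of change** — G likelihood-ratio tests for sex-ratio
  heterogeneity, Kruskal–Wallis tests, and logistic random-intercept
  (per-plot) models of change occurrence on standardised covariates (stem
  diameter, relative light in the leafless and leafy seasons, yearly
  growth), with backward AIC selection (`g_test()`, `kruskal_wallis()`,
  `fit_mixed_logistic()`, `backward_aic()`).

A synthetic census generator (`simulate_census()`) with the same
statistical structure — Markov transitions or covariate-driven change
probabilities, plot random effects, occasional non-flowering years — lets
every stage run and be validated without field data. Two reference fixtures
built from published census summaries ship as plain CSV under
`inst/extdata/`.

## Worked example

```r
library(sexlability)

# reference census of two-year transition pairs (937 events)
census <- read_census(system.file("extdata", "table2_pairs.csv",
                                  package = "sexlability"))
trajs  <- build_trajectories(census)

counts <- count_transitions(trajs)            # 6-state counts
pooled <- pool_counts(counts)                 # F / M / H-all
round(to_probabilities(pooled)$probs, 4)
#>           F      M   HALL
#> F    0.9524 0.0127 0.0349
#> M    0.0170 0.9320 0.0510
#> HALL 0.0701 0.0274 0.9024

steady_state_test(pooled, n_boot = 5000, seed = 1)
#> Steady-state (stationary) sex ratio, 5000 bootstrap replicates (scheme: pooled, seed 1)
#>   state  point boot_mean ci_low ci_high  vs_null
#> 1     F 0.5008    0.5020 0.3468  0.6737 > 0.3333
#> 2     M 0.2101    0.2115 0.0942  0.3561       ns
#> 3  HALL 0.2891    0.2865 0.1791  0.4031       ns
```

Staying as they are, these transition probabilities would carry the
population to roughly 50% females, 21% males and 29% hermaphrodites: the
female share sits significantly above the uniform 1/3 (its whole 95%
interval exceeds it), while the male share falls below 1/3 in point
estimate, with an interval too wide — the inflow from `F` to `M` rests on
very few events — to call it significant from these pooled counts alone.

Pattern analysis on the 309-trajectory fixture:

```r
tabulate_patterns(build_trajectories(read_census(
  system.file("extdata", "table1_trajectories.csv",
              package = "sexlability"))))
#> Sex-change patterns over 309 individuals: 85 changed at least once, 224 constant
#>     pattern      direction n_changes count percent
#> 1         A       constant         0   224    72.5
#> 2       A→B unidirectional         1    37    12.0
#> 3     A→B→A  bidirectional         2    17     5.5
#> ...
```

`run_full_analysis(census_path, out_dir, seed)` wires all stages into one
reproducible report bundle (CSV outputs plus a JSON manifest).

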