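---
title: "Analysing labile sex expression in longitudinal plant censuses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing labile sex expression in longitudinal plant censuses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexlability)
```

## The problem

Subdioecious plants are mostly male or female, with a minority of
hermaphrodites, and individuals can express different sexual phenotypes in
different flowering seasons ("gender lability"). A yearly census of such a
population records, per tagged individual, one of six sexual categories --
female (`F`), male (`M`), hermaphrodite with only perfect flowers (`H`),
and hermaphrodites mixing perfect flowers with pistillate (`HF`), staminate
(`HM`) or both (`HFM`) flower types -- plus non-flowering years (`NF`) and
years with no observation (`NA`). Three questions follow naturally:

1. **How often, and along which paths, does sex change?** Individual
   trajectories are classified into canonical change patterns.
2. **Where is the sex ratio heading?** The year-to-year transitions define a
   discrete-time Markov chain whose stationary distribution is the long-run
   expected sex ratio if transition probabilities stay constant. Bootstrap
   resampling gives confidence intervals and a test against the uniform
   1/3 : 1/3 : 1/3 null.
3. **What covaries with changing sex?** Stem size (DBH, cm), light
   environment (rPPFD, the photon flux above an individual's crown relative
   to an open site, measured in the leafless and leafy seasons) and yearly
   growth (mm/yr, the absolute DBH difference between successive years)
   enter logistic random-intercept models of change occurrence, with
   backward AIC selection.

This vignette explains the model, the numerical choices, what the synthetic
generator does and does not emulate, and the design decisions taken where
the method was genuinely open.

## Transition counting and the Markov model

`count_transitions()` counts a pair (year *t*, year *t+1*) if and only if
both years are present, consecutive, and both states are expressed. `NF` and
`NA` break that pair but not later ones: a plant that flowered in 2010,
skipped 2011 and flowered in 2012 contributes nothing, because its sex in
the gap year is unknown and the census is strictly annual. For 3-state
analyses the four hermaphrodite categories are pooled to `H-all` *before*
counting; pooling commutes with counting (a tested property), so it is
equivalent to aggregating the 6-state matrix.

The internal convention is rows = origin state, so probability matrices are
row-stochastic and Markov algebra reads naturally; the transposed layout
used in printed tables (columns = previous year) is supported at I/O via
`write_matrix(..., orientation = "paper")`.

`stationary()` solves \(\pi P = \pi\), \(\sum_i \pi_i = 1\) as the
least-squares solution of \((P^\top - I)\pi = 0\) stacked with the
normalisation row. Before solving, irreducibility is verified by boolean
reachability on the positive-support graph; reducible chains are refused
with the offending states named, because a stationary distribution of a
reducible chain is not unique and would silently mislead. The solve is
rejected if \(\lVert \pi P - \pi \rVert_\infty > 10^{-10}\). The test suite
cross-checks the solver against an independent power-iteration oracle on
hundreds of random 3x3 and 6x6 chains (agreement to 1e-8).

### Bootstrap and the uniform-null test

`bootstrap_matrices()` resamples the observed transition events and
row-normalises each replicate. The default scheme (`pooled`) treats all
`n_pairs` (origin, destination) events as one exchangeable multiset — a
single multinomial over all cells — which is the simplest scheme consistent
with yearly census pairs; `row-stratified` (independent multinomials per
origin row, row totals fixed) is provided as an alternative and recorded in
the output metadata. Replicates with an empty row or a reducible chain are
rejected and redrawn rather than patched with pseudocounts, which would
bias \(\pi\); after 1000 consecutive rejections the counts are declared
degenerate and an error is raised. Replicate sets are a deterministic
function of the seed, which is mandatory.

`steady_state_test()` computes \(\pi\) for every replicate and reports the
replicate mean and the percentile interval at the requested level (default
95%). A state is called significantly above (below) the null value
(default 1/3) exactly when its whole interval lies above (below) it; no
p-value is attached. Percentile rather than BCa intervals are used to match
the method's plain presentation of bootstrap intervals.

A caution worth stating explicitly: with roughly 900 pooled events the male
component's interval is wide, because the inflow to `M` from `F` rests on
very few events; its spread is dominated by a single low-count cell. Both
provided schemes give an `M` upper bound slightly above 1/3 on the packaged
reference counts, so on these data the package calls `F` significantly above
the null but does not call `M` significantly below it. Narrower intervals
would require resampling the individual-level sequences, which a count
matrix alone cannot reconstruct.

## Pattern taxonomy

`canonicalize()` reduces a trajectory to the sequence of distinct successive
expressed states, relabelled `A, B, C, ...` in order of first appearance:
`[F, M, F]` becomes `A→B→A`. Three decisions matter:

* **Gaps are skipped by default** (`collapse_gaps = TRUE`): `NF`/`NA` years
  are removed before collapsing. Five-symbol patterns are only attainable by
  five uninterrupted flowering years, and the packaged trajectory fixture is
  built under this default. With `collapse_gaps = FALSE` only the first
  maximal run of consecutive-year expressed observations is used, so a
  change is never scored across a year in which sex was unobservable; this
  keeps the invariant `n_changes = symbols - 1` exact in both modes.
* **Consecutive repeats collapse before relabelling**, so `[F, F, M]` and
  `[F, M, M]` are both `A→B`: patterns encode changes, not durations, and
  `n_changes` then matches once/twice/three-times tabulations.
* **Direction** is operationalised as letter reappearance: `bidirectional`
  iff some letter recurs after a different letter intervened, otherwise
  `unidirectional` (or `constant` with no change). This reproduces the
  unidirectional/bidirectional split of all eight observed patterns.

Individuals observed in plots censused for fewer years can attain fewer
changes; `tabulate_patterns()` therefore reports the observation-span
distribution alongside the percentages, which use all classifiable
individuals as the base.

## Covariate models

`change_model_data()` builds one model row per individual-year *t* with a
consecutive year on both sides: year *t-1* supplies the growth measurement
(10·|DBH~t~ − DBH~t−1~| in mm), year *t+1* the binary response (state
changed, or the focal pattern occurred for `from_state`/`to_state`
subsets). This is the only reading under which yearly growth and both rPPFD
seasons are defined for every response; it also mirrors dropping the first
census year when winter light was not yet measured. Covariates are
standardised (mean 0, SD 1) and the constants stored, so coefficients are
comparable effect sizes.

`fit_mixed_logistic()` is a Bernoulli-logit GLMM with a Gaussian random
intercept per plot, maximised by adaptive Gauss–Hermite quadrature
(`lme4::glmer`, 15 nodes by default; one node would be the Laplace
approximation, and 15 is ample for a single scalar random effect). With a
single plot, or `random_effect = FALSE`, it collapses to `stats::glm` — the
zero-variance limit, used as an oracle check in the tests, alongside a
dense-grid numerical integration of the marginal likelihood. Coefficients
are reported without p-values; model comparison is by AIC only.
`backward_aic()` drops, at each step, the term whose removal lowers AIC the
most, stopping when no removal lowers it, with a deterministic tie-break
(the term latest in the declared order is dropped) and a full selection
trace. Non-converged or separated candidate fits are excluded with a
warning. Pattern-specific models should only be read when the focal change
has more than about 10 events; rarer patterns do not support a 4-covariate
model.

## The synthetic census generator

`simulate_census()` exists so that every stage of the pipeline can be
exercised, and its estimators validated by parameter recovery, without any
field data. Its defaults emulate the study conditions: four plots of 74,
81, 102 and 52 individuals, censused 2010–2014; initial states drawn from
the observed average type proportions (F 33.2%, M 30.1%, H 5.1%, HF 22.6%,
HM 4.0%, HFM 2.4%); a per-individual non-flowering probability of 0.08 per
year (the censuses show a visible but minor non-flowering fraction); DBH ~
lognormal(log 3, 0.5) cm and yearly growth ~ Gamma(2, 0.5) mm (a shrub of a
few cm DBH growing ~1 mm/yr); rPPFD-winter ~ Beta(2, 4) and rPPFD-summer ~
Beta(1.5, 6), the leafy season being darker under a closed canopy. Light
and size are drawn once per individual (near-static over five years);
growth is redrawn yearly and accumulated onto DBH so that the derived
growth covariate is exactly the simulated one.

In **matrix mode** next year's state is drawn from the supplied transition
matrix row — the null model of the Markov analysis, used for
round-trip recovery tests (simulate, count, estimate; the estimated matrix
and its stationary vector converge to the generating ones). In **covariate
mode** a change occurs with probability
\(\mathrm{logit}^{-1}(\beta_0 + \beta' x + u_{plot})\) on theoretically
standardised covariates, and the destination is drawn from the origin row's
off-diagonal distribution. The default \(\beta\) uses the reported
standardised occurrence effects (rPPFD-winter 0.343, rPPFD-summer 0.025,
growth 0.164, size not retained) with intercept −2.1, chosen once so the
marginal yearly change probability is about 0.12, close to the observed
six-state rate (133 changes in 937 pairs, ≈ 0.14).

What the generator deliberately does **not** emulate: mortality,
recruitment, spatial structure within plots, pollination dynamics, climate
drivers, or any dependence of the *destination* state on covariates (only
the occurrence of change is covariate-driven). Passing tests therefore
validate the estimators under the model's own assumptions — exchangeable
individuals following a homogeneous chain — not the full complexity of real
censuses.

## Numerical and scale choices

* Probabilities are kept at full precision; 4-decimal rounding is applied
  only at display and in written reports (`%.6f` in CSV output).
* Bootstrap and simulation sizes in the shipped tests were chosen to make
  each stochastic check's false-alarm probability small at desk scale:
  5000 replicates for the reference steady-state run; 150 simulated
  datasets at the reference sample sizes for interval coverage; 100
  simulated censuses of ~4000 usable individual-years for GLMM recovery;
  2000 null replicates for the type-I error of the G and Kruskal–Wallis
  tests.
* The two packaged fixtures are generated by code (`make_fixture_table2()`,
  `make_fixture_table1()`) and shipped as plain CSV. They are synthetic
  reconstructions: one encodes the printed pairwise transition counts as
  independent two-year pseudo-individuals (937 events; the printed table's
  H-column total disagrees with its own cells by one, and the cells are
  taken as authoritative since the steady state reproduces only from them);
  the other encodes the printed pattern counts as 309 trajectories whose
  concrete states never use a never-observed transition. The two fixtures
  are not mutually consistent — each reproduces its own printed table
  exactly, which is all the unpublished raw census allows.
* `run_full_analysis()` wires the stages together with a run manifest
  (input hash, seed, scheme, package version); given the same census and
  seed the analysis outputs are byte-identical. The occurrence model is
  skipped, with a note, when the census carries no covariates. The
  boundary-year sex-ratio comparison is a G-test over the six expressed
  categories between the first and last census years, dropping categories
  absent from both.

## Known limitations

* The bootstrap operates on transition events, not on individuals;
  within-individual correlation of transitions is ignored, which is exact
  for the pair fixture but an approximation for multi-year trajectories.
* The steady state extrapolates a time-homogeneous chain; it is a
  projection of current transition probabilities, not a forecast.
* GLMM coefficient recovery is validated on synthetic data; on real data,
  unmodelled year effects or covariate measurement error would widen the
  true uncertainty beyond the reported standard errors.
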