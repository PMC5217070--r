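# genegroups

Genetic group animal models for pedigreed populations with unknown parents.

## The problem

Animal models — linear mixed models with an individual-level additive genetic
effect whose covariance is σ²<sub>A</sub>**A**, with **A** the numerator
relationship matrix built from a pedigree — are the workhorse of quantitative
genetics in both agriculture and evolutionary ecology. Wild-population
pedigrees, however, almost always contain many individuals with unknown dams
or sires. Every unknown parent is replaced by a *phantom parent* drawn from
the model's base population, which is assumed to have mean breeding value
zero. When the individuals with unknown parents are genetically non-random —
the classic case being immigrants from a diverged source population — this
assumption fails: breeding value predictions regress to the wrong mean,
spurious temporal trends in predicted breeding values appear without any
selection, and the additive genetic variance is badly overestimated.

*Genetic group* methods fix this by partitioning the phantom parents into
groups that are allowed their own mean additive genetic value. This package
implements, for R users working with tidy tabular pedigrees:

- pedigree input, validation, topological ordering and missingness summaries;
- inbreeding coefficients *F*, the dense relationship matrix **A**, Henderson's
  factors **A** = **TDT′**, and the sparse inverse **A**⁻¹ built directly from
  the pedigree;
- the genetic-group machinery: the contribution matrix **Q** (row *i* gives
  the expected fractions of individual *i*'s genome deriving from each group;
  rows sum to one) and the group-augmented sparse inverse **A\*** — with hard
  or fuzzy (probabilistic) phantom-parent classification;
- mixed-model fitting by sparse BLUP with profile REML for
  (σ²<sub>A</sub>, σ²<sub>E</sub>), in three modes:
  - **basic**: `y = Xβ + Za + e` (no groups — the model that goes wrong),
  - **explicit**: `y = Xβ + Qg + Za + e` (group contributions as fixed
    covariate regressions),
  - **implicit**: `y = Xβ + Zu + e` with `u ~ N(Qg, σ²A A)` fitted through
    **A\*** — the two group modes yield identical estimates of **g**, and
    `u = Qg + a` converts between total additive genetic effects and breeding
    values;
- a population simulator with immigrant gene flow that reproduces the bias
  and its correction end to end.

## Worked example

Simulate the default study population — 15 generations × 400 individuals,
40 immigrants per generation whose total additive genetic effects average 3
units above the founders, σ²<sub>A</sub> = σ²<sub>E</sub> = 1 — then fit the
two-group model to the observed (masked) pedigree:

```r
library(genegroups)

sim <- simulate_population(sim_params(), seed = 42)
sim
#> Simulated population: 6000 individuals, 15 generations, 40 immigrants/generation (mean shift +3)
#>   sigma2_A = 1, sigma2_E = 1, seed = 42

missingness_summary(sim$masked_pedigree)
#> # A tibble: 1 × 7
#>   n_total n_unknown_dam n_unknown_sire pct_unknown_dam pct_unknown_sire ...
#> 1    6000           960            960              16               16

gped <- assign_groups(sim$masked_pedigree, rule = "flag")  # founder vs immigrant
fit  <- fit_animal_model(gped, sim$truth[c("id", "y")], mode = "explicit")
fit
#> Animal model fit (mode = explicit), 6000 records
#>   sigma2_A = 0.9526, sigma2_E = 1.0411
#>   genetic group effects (reference = founder):
#>     founder        0.0000  (se --)
#>     immigrant      2.9856  (se 0.0829)

tidy(fit)
#> # A tibble: 2 × 5
#>   term            estimate std.error statistic    p.value
#> 1 group_founder       0      NA           NA   NA
#> 2 group_immigrant     2.99    0.0829      36.0  5.65e-284
```

The grouped model recovers the simulated immigrant–founder contrast (3) and
the founder additive variance (1). The basic model, fitted to the same data,
shows the bias the package exists to correct:

```r
glance(fit_animal_model(sim$masked_pedigree, sim$truth[c("id", "y")], mode = "basic"))
#> # A tibble: 1 × 7
#>   mode   nobs sigma2_A sigma2_E lambda  loglik converged
#> 1 basic  6000     1.91    0.796  0.417 -10712. TRUE
```

σ̂²<sub>A</sub> ≈ 1.9: roughly twice the true founder value, purely because
immigrants with unknown parents were folded into a single base population.
`autoplot(fit)` shows the companion diagnosis: with groups modelled,
cohort-mean breeding values are flat while total additive genetic effects
rise with gene flow; without groups, predicted breeding values carry a
spurious upward trend.

A shell interface wrapping the same functions is available via
`gg_cli()` / `inst/cli/genegroups.R` (subcommands `simulate`, `ainv`, `qmat`,
`astar`, `fit`, `reml`, `summary`), writing CSV tables and lower-triangle
sparse triplet files.

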