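# weanabc

Quantitative reconstruction of breastfeeding and weaning practices in past
human populations from cross-sectional bone collagen nitrogen isotope data.

## The problem

Nursing infants feed one trophic level above their mothers, so the δ15N of
collagen they synthesize is elevated by an enrichment factor *E* (typically
2–3 ‰) over the maternal value. As weaning foods replace breast milk between
the ages *t1* (start of weaning) and *t2* (end of weaning), newly synthesized
collagen declines toward the value fixed by the weaning foods, δ15N_wnfood.
Bone, however, is an archive with inertia: bulk bone collagen mixes new
collagen into old at the bone turnover rate, which is very high in infancy
(>1/yr) and falls steadily through childhood. Reading weaning ages directly
off subadult δ15N–age scatterplots therefore misdates the transition, and
does so worse at older ages.

`weanabc` addresses this for osteological assemblages in three steps:

1. **Turnover.** Subadult cancellous-bone collagen turnover is derived from
   tissue-level physiology: a skeletal mineral growth curve M(x) plus an
   age-dependent remodeling rate R(x) give the per-year mineral turnover
   `k_m(x) = (M(x+1) − M(x) + R̄(x)·M(x)) / M(x+1)`, and the collagen
   turnover `k_c` is obtained by deconvolving the mineralization delay
   (newly formed collagen matrix mineralizes to ~83 % within its first year
   and acquires the remainder over years):
   `k_m(x) = Σ_l w_l · k_c(x − l)`. The twenty discrete rates are condensed
   into a quartic polynomial (QP) in age used by the simulator.
2. **Forward model.** Given (t1, t2, E, δ15N_wnfood) and the maternal value
   (the adult-female mean), the δ15N of newly synthesized collagen is a
   plateau–exponential–plateau curve; bulk bone starts at the maternal value
   at birth and, over each one-year unit, mixes in newly synthesized
   collagen at the integrated turnover for the unit (capped at complete
   replacement), with a fractional final unit serving each individual's age
   at death.
3. **Inference.** The four weaning parameters are estimated by approximate
   Bayesian computation with sequential Monte Carlo sampling and partial
   rejection control, using the mean squared distance between observed and
   simulated δ15N. The weighted posterior is smoothed by kernel density
   estimation, discretized to 0.1-unit cells, and reported as maximum
   density estimators (MDEs) with cell probabilities, discrete range
   probabilities, and weighted credible intervals.

## Worked example

```r
library(weanabc)

## the turnover table (fraction of bone replaced per year)
tab <- turnover_table()
head(round(tab, 3), 3)
#>   from to mineral collagen collagen_qp
#> 1    0  1   1.217    1.474       1.413
#> 2    1  2   0.908    1.059       1.134
#> 3    2  3   0.786    0.892       0.924
integrated_turnover(attr(tab, "qp"), 0, 1)
#> [1] 1.587906   # an infant's collagen is fully renewed within the first year

## a bundled synthetic assemblage (20 subadults; simulated from known
## truth t1 = 1.0 y, t2 = 3.0 y, E = 2.4, wnfood = 9.5 with the adult
## mean at 10.0)
pop <- read_population_csv(
  system.file("extdata", "example_population_synthetic.csv", package = "weanabc"),
  system.file("extdata", "example_adults_synthetic.csv", package = "weanabc"))

fit <- run_smc(pop, config = smc_config(n_particles = 2000, n_stages = 9,
                                        seed = 1))
posterior_summary(fit)
#> Weaning-model posterior summary
#>   MDE: t1 = 1.0 y, t2 = 3.1 y, E = 2.7 permil, wnfood = 9.6 permil
#>   delta_wnfood (vs all-adult mean): -0.40 permil
#>   cell probabilities: joint(t1,t2) = 0.0040, E = 0.111, wnfood = 0.137
#>   95% CI t1         [0.08, 1.58]
#>   95% CI t2         [1.86, 5.18]
#>   95% CI enrichment [2.15, 3.49]
#>   95% CI wnfood     [9.04, 9.94]
```

The MDEs are the grid cells of maximum smoothed posterior density; weaning
is estimated to start around 1.0 y and end around 3.1 y (truth: 1.0 and
3.0). `delta_wnfood` is the weaning-food collagen value relative to the
all-adult mean; negative values indicate lower-trophic-level weaning foods
(cereals, legumes) — here −0.4 ‰ against a true −0.5 ‰. The cell
probabilities quantify how concentrated the posterior is; fits whose joint
(t1, t2) cell mass falls below 0.0025, whose marginal cell mass falls below
0.05, or whose `delta_wnfood` is more negative than −E are flagged as
suspect. `plot(posterior_summary(fit), data = pop)` draws the fitted
trajectory, the joint (t1, t2) posterior and the two marginals.

Real data use the same CSV layout as the bundled example: one subadult per
row (`id, age, d15n`) plus an adult sidecar (`group, mean, sd` with rows
`adult_female` and `adult_all`). A command-line wrapper with `turnover`,
`simulate`, `synth`, `fit` and `summarize` subcommands is installed at
`inst/cli/weanabc.R`.

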