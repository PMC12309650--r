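# trendrisk

Population trends and IUCN extinction-risk categories from wildlife
monitoring data — estimated two ways, from *occupancy* (detection /
non-detection histories) and from *abundance* (counts), with full posterior
uncertainty carried into the final threat classification so the two routes
can be compared honestly.

The package is aimed at ecologists running or analysing multi-season
monitoring programmes (the motivating case is amphibian breeding-site
surveys: frog egg-clutch counts and adult newt counts) who need to know not
just *whether* a population is declining but how the answer depends on the
data type used to ask.

## What it computes

**Trend models.** Three Bayesian hierarchical models share the linear
predictor `alpha + beta_trend * year_c + T_t + S_i` (year and site random
effects, year centered):

- `fit_occupancy()` — multi-year site-occupancy model with imperfect
  detection: `z[i,t] ~ Bern(psi)`, `y[i,j,t] | z ~ Bern(z * p)`, with
  `logit(p)` a quadratic in survey date and time of day;
- `fit_abundance_glmm()` — negative-binomial count model (mean/size
  parameterization) for census-quality counts such as egg-clutch counts;
- `fit_nmixture()` — binomial mixture for seasonal maximum counts:
  `N ~ NegBin(mu, size)`, `y | N ~ Bin(N, p)`, with the latent `N`
  marginalized in closed form.

Sampling is by a compiled adaptive Metropolis-within-Gibbs scheme over
marginalized likelihoods (no discrete latent variables), with split-chain
Rhat convergence checks.

**Derived decline statistics.** Posterior draws are pushed through, per
draw: yearly indices (occupied sites, total abundance), period means over
assessment periods (default 1996–2003, 2004–2011, 2017–2022), between-period
change `C = mean_b/mean_a − 1`, decline probability `Dp = Pr(C < 0)`, annual
decline `Da = 1 − (1 − D)^(1/L)`, and the decline rate over the IUCN window
`Dr = 1 − (1 − Da)^GL` with `GL` the longer of 10 years and 3 generation
lengths.

**Classification.** `Dr` maps to the criterion-A2 ladder (LC < 20% ≤ NT <
30% ≤ VU < 50% ≤ EN < 80% ≤ CR), either for the posterior-median rate or as
a full posterior distribution over categories; `compare_data_types()`
reports the signed category-rank gap between the occupancy-based and
abundance-based assessments.

**Synthetic data.** `sim_config()` + `simulate_*_dataset()` generate
monitoring data with known truth (including a coupled mode where occupancy
is `1{N > 0}`, so abundance declines proportionally faster than occupancy —
the scenario in which the two data types disagree most).

## Worked example

Simulate a coupled decline (80 sites, 1996–2022 with a 2012–2016 gap,
abundance trend −0.08/yr on the log scale), fit both models at reduced MCMC
scale, and assess both data types over the default periods with a 12-year
assessment window:

```r
library(trendrisk)

cfg <- run_config(
  sim = sim_config(n_sites = 80, years = c(1996:2011, 2017:2022),
                   visits_per_year = 4, years_per_site = NULL,
                   alpha_abund = log(8), beta_trend = -0.08,
                   sigma_site = 0.8, sigma_year = 0.2, nb_dispersion = 1.5,
                   newt_p = 0.6, protocol = "adult-count",
                   center_year = 2009, coupled = TRUE, seed = 1),
  mcmc = mcmc_config(n_chains = 3, n_iterations = 4000, n_burnin = 1000,
                     thin_to = 1000, seed = 2),
  periods = default_periods(), gl = 12, species = "smooth_newt_synthetic",
  seed = 3)
run <- run_pipeline(cfg)
run
#> Occupancy vs abundance assessment
#>
#>                species period_pair category_occ category_abund    Dp_occ
#>  smooth_newt_synthetic   tau1-tau2           LC             EN 0.9996667
#>  smooth_newt_synthetic   tau2-tau3           LC             EN 1.0000000
#>  Dp_abund rate_median_occ rate_median_abund ci_width_occ ci_width_abund
#>         1     -0.05964793        -0.6244098   0.07134370     0.10333918
#>         1     -0.10751881        -0.5805229   0.09145007     0.09153407
#>  rank_difference category_distance
#>                3                 3
#>                3                 3
```

Reading the output: both data types are almost certain the population is
declining (`Dp` near 1), but the *occupancy* decline rate over the 12-year
window is ~6–11% (LC), while the *abundance* rate is ~58–62% (EN) — three
Red List categories apart on identical site visits, with the wider credible
interval on the abundance side. That gap is the expected signature of a
population losing individuals faster than it loses sites.

The fitted models are ordinary S3 objects:

```r
run$fit_occupancy
#> Occupancy trend model (imperfect detection)
#>   80 sites, 22 years (1996-2022), year 2006.5 centered to 0
#>   3000 posterior draws (3 chains x 1000)
#>   beta_trend: -0.1086 [-0.1876, -0.0564] per year
#>   max Rhat (key parameters): 1.066

round(assess(run$abund$declines[["tau2-tau3"]], "draws"), 3)
#>    LC    NT    VU    EN    CR
#> 0.000 0.000 0.001 0.999 0.000
```

`summary()`, `coef()` and `predict()` (yearly index with or without year
random effects) work on every fit; `write_draws_csv()` and the pipeline's
`out_dir` argument persist draws, reports and a reproducibility manifest.

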