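---
title: "Estimating population trends and extinction risk from occupancy and abundance data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating population trends and extinction risk from occupancy and abundance data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trendrisk)
```

## The problem

Long-term monitoring programmes record two fundamentally different signals
about a population: whether a species is *present* at a site
(detection/non-detection over repeated visits) and *how many* individuals
(or breeding attempts) are there (counts). Threat assessments under IUCN
Red List criterion A2 are driven by the estimated reduction of the
population over a fixed window — the longer of 10 years and three
generation lengths — and the answer can differ sharply depending on which
signal the reduction is estimated from. A population can lose most of its
individuals while every site still holds a few, so occupancy reacts late
and weakly to a decline that abundance shows early and steeply; conversely
count data are noisier, so abundance-based assessments carry wider credible
intervals.

`trendrisk` implements both estimation routes on the same survey data and
carries posterior uncertainty through every derived quantity, so the two
resulting threat classifications can be compared honestly.

## Models

### Occupancy with imperfect detection

For site $i$, year $t$ and within-season visit $j$:

$$z_{it} \sim \mathrm{Bernoulli}(\psi_{it}), \qquad
\mathrm{logit}(\psi_{it}) = \alpha + \beta_{\mathrm{trend}}\,\mathrm{year}_t
+ T_t + S_i$$

$$y_{ijt} \mid z_{it} \sim \mathrm{Bernoulli}(z_{it}\, p_{ijt}), \qquad
\mathrm{logit}(p_{ijt}) = \alpha_p + Sp_i + \beta_1 d_{ijt} + \beta_2
d_{ijt}^2 + \beta_3 h_{ijt} + \beta_4 h_{ijt}^2$$

where $\mathrm{year}_t$ is the calendar year centered (by default at the
median surveyed year; production runs on the original monitoring data used
2009), $T_t$ and $S_i$ are year and site random effects, and the detection
covariates are day of year ($d$) and minutes after 06:00 ($h$), capturing
seasonal and diel phenology of detectability. Date and hour are
standardized to mean 0, SD 1 inside the fitting function — the sampler is
far better behaved on that scale — and the constants are stored in the fit
so predictions and likelihood evaluations are reproducible.

### Abundance

Counts are first collapsed to the seasonal maximum per site-year
(`aggregate_max_count()`), the standard index when within-season replicates
are not independent samples of a closed population. Latent abundance
follows a negative binomial around a log-linear trend:

$$N_{it} \sim \mathrm{NB}(\mu_{it}, r), \qquad
\log(\mu_{it}) = \alpha + \beta_{\mathrm{trend}}\,\mathrm{year}_t + T_t +
S_i$$

parameterized by mean and size ($\mathrm{Var} = \mu + \mu^2/r$) — we state
this explicitly everywhere because the alternative parameterization is a
classic source of silent errors. Two observation models connect $N$ to the
data:

* **Census counts** (`fit_abundance_glmm()`): the observed count *is* $N$.
  Appropriate for indices with near-perfect detectability, such as
  brown-frog egg-clutch counts (detection > 90%).
* **Binomial mixture** (`fit_nmixture()`): the seasonal maximum count is
  $y_{it} \mid N_{it} \sim \mathrm{Binomial}(N_{it}, p)$ with a single
  detection probability $p \sim \mathrm{Uniform}(0,1)$. Detection is
  intercept-only because the max-aggregation destroys the visit-level
  covariate structure.

A useful identity drives the implementation: binomial thinning of a
negative binomial is again negative binomial,
$\sum_N \mathrm{NB}(N;\mu,r)\,\mathrm{Bin}(y;N,p) = \mathrm{NB}(y;
p\mu, r)$ (mix a thinned Poisson over its gamma-distributed rate). The
sampler therefore never visits the latent $N$; the explicitly truncated sum
is also implemented (`nmixture_marginal_loglik()`, truncation bound the
larger of three times the maximum count and the $1-10^{-8}$ negative
binomial quantile) and the test suite checks the two routes agree. A
corollary worth stating plainly: with one count per season, $p$ enters the
likelihood only through the product $p\mu$, so it is informed almost
entirely by its prior and the abundance intercept absorbs the rest. The
trend — the quantity the assessment needs — remains identified, and fits
with and without the detection layer give closely consistent trends
(`detection = FALSE` collapses the model to the census variant exactly).
We keep the detection variant as the default for newt-style data because it
represents the count error mechanism honestly in the posterior width.

### Priors

Fixed-effect slopes and detection coefficients: Normal(0, sd 10)
(precision 0.01). Occupancy intercept: the prior induced by mean occupancy
$\sim$ Uniform(0,1), i.e. standard logistic on the logit scale — a uniform
prior placed on the *logit* scale over (0,1) would confine average
occupancy to [0.5, 0.73], which is not a sensible prior for declining
populations. Abundance intercept: Uniform(−10, 10) on the log scale.
Random-effect standard deviations: Uniform(0, 10). NB size: Uniform(0, 50),
spanning strong overdispersion to near-Poisson. Newt detection
probability: Uniform(0, 1).

## Sampling

Fitting is by an adaptive Metropolis-within-Gibbs sampler written in C++,
operating on marginalized likelihoods: the occupancy likelihood sums the
latent state out of each site-year factor
($\psi \prod_j p^y (1-p)^{1-y} + (1-\psi)\,\mathbf{1}\{\text{all } y=0\}$),
and the count models use the thinned-NB closed form. Removing the discrete
latent variables is what makes desk-scale inference fast and well mixed.
Each scalar parameter takes a Gaussian random-walk update whose scale
adapts during burn-in toward 44% acceptance and is frozen afterwards; site
and year effects use likelihood locality (a site update touches only that
site's rows). Three translation ("ridge") moves handle the exactly or
nearly confounded directions — intercept vs the mean of site effects,
trend vs year effects, and $\log p$ vs the abundance intercept — at
prior-only cost; without them these ridges dominate the autocorrelation
time. Cached likelihood contributions are refreshed from scratch every 500
sweeps to stop numerical drift.

Defaults follow the production convention (3 chains × 400,000 iterations,
300,000 burn-in, thinned to 1000 retained draws per chain). Everything in
the test suite and the acceptance script runs a reduced configuration —
3 × 4000 iterations, 1000 burn-in, with around 100 sites, 15–22 years and
3–5 visits — chosen as the smallest scale at which the recovery studies
have useful power. Convergence is monitored with classic split-chain
$\hat R$ (each chain halved, between/within variance compared; no rank
normalization) and the pipeline refuses to emit an assessment when
$\hat R > 1.1$ for an intercept or trend unless forced.

Chains are initialized from data-driven central values (naive occupancy,
log mean count) independently jittered per chain, with random-effect SDs
drawn from (0.2, 1). All randomness flows from one seed: identical
configurations give bit-identical draws.

## From posterior draws to threat categories

Every derived quantity is computed per posterior draw first and summarized
last, so the credible interval of, say, a decline rate reflects full
parameter uncertainty. In order:

1. **Yearly index.** Per draw and year, the expected number of occupied
   sites $\sum_i \mathrm{logistic}(\alpha + \beta t \,[+ T_t] + S_i)$ or
   total abundance $\sum_i \exp(\cdots)$. Study-period *endpoints*
   (proportional change over the whole series) exclude the year effects —
   they are random fluctuations, not trend — while *period means* include
   them, averaging realized fluctuations across each period's years. Both
   conventions are exposed via `include_year_effects`; these defaults are
   our reading of the standard practice, and the choice matters little when
   periods span several years. Year effects for never-surveyed years are
   drawn from their prior $N(0, \sigma_T)$.
2. **Periods.** The default split is 1996–2003, 2004–2011 and 2017–2022
   (the monitoring gap 2012–2016 belongs to no period). Elapsed time
   between periods is the difference of their mean calendar years — 8 and
   12 years for the defaults — the only simple definition consistent with
   both values.
3. **Decline.** Per draw, $C = \bar{n}_b/\bar{n}_a - 1$ (signed; negative
   means decline) and $D = -C$. The *decline probability* $D_p$ is the
   fraction of draws with $C < 0$ (draws exactly at 0 count as
   non-decline). $D$ is annualized, $D_a = 1-(1-D)^{1/L}$, and compounded
   over the assessment window, $D_r = 1-(1-D_a)^{GL}$, with $GL \ge 10$
   years (three generation lengths if longer; a per-species configuration
   value). The reported rate is $-D_r$, so printed medians are negative
   for declines and intervals can span positive values — increases are
   never clipped. Draws in which a population is entirely absent in the
   earlier period are excluded and counted; $D \ge 1$ maps to rate 1 and is
   flagged.
4. **Classification.** $D_r$ (positive-decline scale) maps to LC < 20%,
   NT ≥ 20%, VU ≥ 30%, EN ≥ 50%, CR ≥ 80%, thresholds inclusive upward;
   increases classify as LC. The 20% NT rung is a common
   flagging convention layered onto the A2 thresholds rather than part of
   the formal criterion. `assess()` classifies the posterior-median rate by
   default (median-of-derived, consistent with the per-draw philosophy) or
   returns the full posterior over categories, which is the honest way to
   show how uncertain an assessment is. For plots, decline probabilities
   can be spread with $-\log(1-D_p)$, capping $D_p = 1$ at the resolution
   of the posterior sample ($1 - 1/n_{\text{draws}}$).

Before fitting abundance models the site set can be restricted to sites
within 1500 m (inclusive) of an ever-occupied site — the typical maximum
dispersal distance for pond-breeding amphibians — so that structurally
unreachable sites do not dilute the trend or inflate totals.

## The synthetic-data generator

`sim_config()` defaults emulate the structure of a long-term amphibian
monitoring programme: 212 wetland sites over 1996–2022 with no surveys in
2012–2016, each site sampled in 2–9 years, 2–8 visits per sampled year
within a February–June breeding window (day of year 32–181), by day and
night (minutes after 06:00 in 0–1080). Trend, random-effect and dispersion
values are not published quantities; the defaults (trend −0.05/yr, site SD
1, year SD 0.3, NB size 1.5, newt per-visit detection 0.6) were chosen once
as values a field ecologist would call realistic for declining amphibian
populations in fragmented landscapes. Occupancy and abundance truths are
generated by independent processes by default, mirroring the two separate
models; `coupled = TRUE` instead derives occupancy from latent abundance
($z = \mathbf 1\{N>0\}$), the scenario in which abundance declines
proportionally faster than occupancy — used by the comparison tests and the
acceptance script.

What the generator does *not* emulate: spatial autocorrelation and
dispersal dynamics, weather-driven detectability, observer effects, or the
empirical distribution of real visit dates and times (visits are uniform
within the breeding window). Passing recovery tests on generated data
therefore shows the estimators are correct *under the model assumptions*,
not that real data meet those assumptions.

## Numerical and design notes

* The occupancy site-year factor is evaluated as
  $\log(1+e^{\ell+A}) - \log(1+e^{\ell})$ for all-zero histories
  ($\ell$ the occupancy logit, $A$ the detection log-product), which is
  stable for $\psi \to 0$ and $\to 1$.
* The truncated N-mixture sum changes by less than $10^{-6}$ when the
  bound doubles (tested), and the `det_p = 1` limit equals the NB pmf to
  machine precision.
* Aggregation keeps all-zero site-years as observed zeros; zeros are data.
* Sites never surveyed are dropped with a warning; fits require at least
  two distinct years.
* `elapsed_years()` of identical periods is 0 and is rejected by the
  decline preconditions rather than producing an infinite annual rate.
* Ties at category thresholds go to the higher (more threatened) category,
  following the "≥" reading of the thresholds.

## Limitations

The models estimate a single log- or logit-linear trend with exchangeable
year effects; they do not model density dependence, open-population
dynamics (recruitment/survival), zero inflation, or spatial correlation
between sites. The binomial-mixture detection probability is, by
construction, barely identified from single seasonal counts — its role is
to widen the posterior honestly, not to estimate detectability. Extreme
declines ($D \to 1$) saturate the rate scale, and assessments repeated over
successive periods are not independent, so a category can improve while a
population keeps declining — an interpretive caveat, not a computational
one.
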