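test_that("marginal likelihood matches exhaustive z-enumeration", {
  cases <- expand.grid(n_sites = c(1, 2, 3), n_years = c(1, 2),
                       n_visits = c(1, 3))
  for (r in seq_len(nrow(cases))) {
    d <- tiny_occu_data(cases$n_sites[r], cases$n_years[r],
                        cases$n_visits[r], seed = r)
    p <- tiny_occu_params(unique(d$site_id), unique(d$year), seed = r + 50)
    expect_equal(occupancy_marginal_loglik(p, d), enum_occu_loglik(p, d),
                 tolerance = 1e-10)
  }
})

test_that("marginal likelihood limits: forced presence and certain absence", {
  d <- tiny_occu_data(2, 1, 2, seed = 4)
  p <- tiny_occu_params(unique(d$site_id), unique(d$year), seed = 60)
  # a site with a detection contributes psi * prod Bern(y | p)
  d$detect <- c(1, 0, 0, 0)   # site 1 detected once, site 2 never
  ll <- occupancy_marginal_loglik(p, d)
  expect_true(is.finite(ll))
  # psi -> 0 with all-zero histories: likelihood 1
  p0 <- p; p0$alpha <- -1e6
  d0 <- d; d0$detect <- 0L
  expect_equal(occupancy_marginal_loglik(p0, d0), 0)
  # psi -> 0 with a detection: impossible data
  expect_equal(occupancy_marginal_loglik(p0, d), -Inf)
})

test_that("conditional occupancy cannot decrease when a detection is added", {
  # P(z = 1 | history) under fixed parameters, via the marginal likelihood
  d <- tiny_occu_data(1, 1, 3, seed = 11)
  p <- tiny_occu_params(unique(d$site_id), unique(d$year), seed = 61)
  post_z <- function(detect) {
    d$detect <- detect
    if (any(detect == 1)) return(1)  # z forced to 1
    marg <- exp(occupancy_marginal_loglik(p, d))
    lp_occ <- p$alpha + p$beta_trend * d$year[1] +
      p$T[[as.character(d$year[1])]] + p$S[[d$site_id[1]]]
    psi <- plogis(lp_occ)
    lp_det <- p$alpha_p + p$Sp[[d$site_id[1]]] +
      p$beta_det[1] * d$doy + p$beta_det[2] * d$doy^2 +
      p$beta_det[3] * d$minutes_after_6 + p$beta_det[4] * d$minutes_after_6^2
    psi * prod(1 - plogis(lp_det)) / marg
  }
  base <- post_z(c(0L, 0L, 0L))
  expect_lt(base, 1)
  expect_gte(post_z(c(1L, 0L, 0L)), base)
})

test_that("sampler log-likelihood agrees with the marginal-likelihood function", {
  cfg <- sim_config(n_sites = 20, years = 2001:2006, visits_per_year = 3,
                    years_per_site = NULL, center_year = 2003, seed = 77)
  d <- simulate_occupancy_dataset(cfg)
  fit <- suppressWarnings(
    fit_occupancy(d$survey, quick_mcmc(seed = 5), center_year = 2003))
  dat <- d$survey
  dat$doy <- (dat$doy - fit$standardization["doy_mean"]) /
    fit$standardization["doy_sd"]
  dat$minutes_after_6 <-
    (dat$minutes_after_6 - fit$standardization["minutes_mean"]) /
    fit$standardization["minutes_sd"]
  for (k in c(1, 500, 1000)) {
    params <- list(
      alpha = fit$draws$alpha[k], beta_trend = fit$draws$beta_trend[k],
      T = fit$draws$T[k, ], S = fit$draws$S[k, ], Sp = fit$draws$Sp[k, ],
      alpha_p = fit$draws$alpha_p[k], beta_det = fit$draws$beta_det[k, ],
      center_year = fit$center_year)
    expect_equal(occupancy_marginal_loglik(params, dat),
                 fit$draws$loglik[k], tolerance = 1e-8)
  }
})

test_that("saturated data pushes occupancy toward one", {
  cfg <- sim_config(n_sites = 50, years = 2000:2004, visits_per_year = 5,
                    years_per_site = NULL, alpha_occ = 10, beta_trend = 0,
                    sigma_site = 0, sigma_year = 0, sigma_site_det = 0,
                    det_params = c(20, 0, 0, 0, 0), center_year = 2002,
                    seed = 15)
  d <- simulate_occupancy_dataset(cfg)
  fit <- suppressWarnings(
    fit_occupancy(d$survey, quick_mcmc(seed = 2), center_year = 2002))
  idx <- predict_yearly_occupied(fit, include_year_effects = FALSE)
  mean_psi <- rowMeans(unclass(idx)) / 50
  expect_gt(quantile(mean_psi, 0.025), 0.8)
})

test_that("fits are deterministic given a seed and respect prior supports", {
  cfg <- sim_config(n_sites = 15, years = 2001:2004, visits_per_year = 2,
                    years_per_site = NULL, center_year = 2002, seed = 3)
  d <- simulate_occupancy_dataset(cfg)
  f1 <- suppressWarnings(
    fit_occupancy(d$survey, quick_mcmc(seed = 9), center_year = 2002))
  f2 <- suppressWarnings(
    fit_occupancy(d$survey, quick_mcmc(seed = 9), center_year = 2002))
  expect_identical(f1$draws, f2$draws)
  for (s in c("sigma_T", "sigma_S", "sigma_Sp")) {
    expect_true(all(f1$draws[[s]] >= 0 & f1$draws[[s]] <= 10))
  }
})

test_that("input validation catches malformed survey data", {
  cfg <- sim_config(n_sites = 10, years = 2001:2003, seed = 1)
  d <- simulate_occupancy_dataset(cfg)$survey
  bad <- d; bad$detect[1] <- 2L
  expect_error(fit_occupancy(bad, quick_mcmc()), "0/1")
  one_year <- d[d$year == min(d$year), ]
  expect_error(fit_occupancy(one_year, quick_mcmc()), "2 distinct years")
  none <- d; none$detect <- 0L
  w <- capture_warnings(fit_occupancy(none, quick_mcmc()))
  expect_true(any(grepl("weakly identified", w)))
})

test_that("yearly occupied index reproduces direct arithmetic", {
  # all sites certain occupied
  f <- fake_fit(alpha = rep(20, 3), beta_trend = rep(0, 3),
                S = c(0, 0, 0, 0), years = 1:3)
  idx <- predict_yearly_occupied(f)
  expect_equal(unclass(idx), matrix(4, 3, 3), ignore_attr = TRUE)
  # logistic(0) = 0.5 per site
  f0 <- fake_fit(alpha = rep(0, 2), beta_trend = rep(0, 2),
                 S = c(0, 0), years = 1:3)
  expect_equal(unclass(predict_yearly_occupied(f0)),
               matrix(1, 2, 3), ignore_attr = TRUE)
  # hand-built single draw at year 4
  f1 <- fake_fit(alpha = 0.3, beta_trend = -0.05, S = c(0.1, -0.2),
                 years = c(1, 4))
  idx1 <- predict_yearly_occupied(f1, years = 4)
  expect_equal(as.numeric(idx1),
               plogis(0.3 - 0.05 * 4 + 0.1) + plogis(0.3 - 0.05 * 4 - 0.2))
  # years outside the fitted range need the explicit flag
  expect_error(predict_yearly_occupied(f1, years = 9), "extrapolate")
  expect_silent(predict_yearly_occupied(f1, years = 9, extrapolate = TRUE))
})

test_that("year effects enter the index only on request", {
  Tm <- matrix(c(0.5, -0.5), 1, 2, dimnames = list(NULL, c("1", "2")))
  f <- fake_fit(alpha = 0, beta_trend = 0, S = 0, years = 1:2, T_draws = Tm)
  trend_only <- predict_yearly_occupied(f, include_year_effects = FALSE)
  with_T <- predict_yearly_occupied(f, include_year_effects = TRUE)
  expect_equal(as.numeric(trend_only), c(0.5, 0.5))
  expect_equal(as.numeric(with_T), c(plogis(0.5), plogis(-0.5)))
})
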