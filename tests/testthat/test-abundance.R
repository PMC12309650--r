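test_that("seasonal maximum aggregation keeps zeros and records visits", {
  sv <- data.frame(site_id = c("a", "a", "a", "b", "c", "c"),
                   year = c(2001, 2001, 2001, 2001, 2001, 2002),
                   visit = c(1, 2, 3, 1, 1, 1),
                   doy = 50, minutes_after_6 = 100,
                   detect = 1L, count = c(3L, 5L, 2L, 4L, 0L, 0L),
                   x_coord = 0, y_coord = 0)
  agg <- aggregate_max_count(sv)
  expect_equal(agg$count[agg$site_id == "a"], 5L)
  expect_equal(agg$count[agg$site_id == "b"], 4L)
  expect_equal(agg$count[agg$site_id == "c"], c(0L, 0L))
  expect_equal(agg$n_visits[agg$site_id == "a"], 3L)
  sv$count[1] <- -1L
  expect_error(aggregate_max_count(sv), "non-negative")
})

test_that("binomial-mixture marginal matches explicit truncated summation", {
  counts <- data.frame(site_id = "s1", year = 2000, count = 0L)
  params <- list(alpha = 0, beta_trend = 0,
                 T = c("2000" = 0), S = c(s1 = 0),
                 nb_dispersion = 1, det_p = 0.5, center_year = 2000)
  # mu = 1, size = 1, p = 0.5, y = 0
  expect_equal(nmixture_marginal_loglik(params, counts, K = 500),
               log(brute_nmix_prob(0, 1, 1, 0.5)), tolerance = 1e-12)
  for (y in c(1L, 4L, 9L)) {
    counts$count <- y
    params$alpha <- log(3.2)
    params$nb_dispersion <- 1.7
    params$det_p <- 0.35
    expect_equal(nmixture_marginal_loglik(params, counts),
                 log(brute_nmix_prob(y, 3.2, 1.7, 0.35)), tolerance = 1e-8)
  }
})

test_that("detection probability one collapses the mixture to the NB pmf", {
  counts <- data.frame(site_id = rep(c("s1", "s2"), each = 3),
                       year = rep(2000:2002, 2),
                       count = c(0L, 3L, 7L, 1L, 0L, 12L))
  params <- list(alpha = log(4), beta_trend = -0.1,
                 T = c("2000" = 0.1, "2001" = -0.2, "2002" = 0),
                 S = c(s1 = 0.3, s2 = -0.4),
                 nb_dispersion = 2.5, det_p = 1, center_year = 2001)
  mu <- exp(log(4) - 0.1 * (counts$year - 2001) +
              params$T[as.character(counts$year)] +
              params$S[counts$site_id])
  direct <- sum(dnbinom(counts$count, mu = mu, size = 2.5, log = TRUE))
  expect_equal(nmixture_marginal_loglik(params, counts), direct,
               tolerance = 1e-12)
})

test_that("the truncated sum is stable when the bound doubles", {
  counts <- data.frame(site_id = "s1", year = 2000, count = 5L)
  params <- list(alpha = log(6), beta_trend = 0, T = c("2000" = 0),
                 S = c(s1 = 0), nb_dispersion = 0.8, det_p = 0.4,
                 center_year = 2000)
  base <- nmixture_marginal_loglik(params, counts)
  K0 <- max(3 * 5, qnbinom(1 - 1e-8, mu = 6, size = 0.8))
  doubled <- nmixture_marginal_loglik(params, counts, K = 2 * K0)
  expect_lt(abs(base - doubled), 1e-6)
  expect_error(nmixture_marginal_loglik(params, counts, K = 3), "at least")
})

test_that("degenerate limits of the mixture likelihood behave", {
  counts <- data.frame(site_id = "s1", year = 2000, count = 0L)
  params <- list(alpha = -10, beta_trend = 0, T = c("2000" = 0),
                 S = c(s1 = 0), nb_dispersion = 1, det_p = 0.5,
                 center_year = 2000)
  # mu -> 0: P(y = 0) -> 1
  expect_equal(nmixture_marginal_loglik(params, counts), 0,
               tolerance = 1e-4)
})

test_that("count-model recovery on simulated clutch data", {
  cfg <- sim_config(n_sites = 60, years = 2001:2012, visits_per_year = 1,
                    years_per_site = NULL, alpha_abund = log(6),
                    beta_trend = -0.06, sigma_site = 0.4, sigma_year = 0.15,
                    nb_dispersion = 2, protocol = "clutch-count",
                    center_year = 2006, seed = 19)
  d <- simulate_abundance_dataset(cfg)
  counts <- aggregate_max_count(d$survey)
  fit <- suppressWarnings(
    fit_abundance_glmm(counts, quick_mcmc(seed = 4, chains = 3),
                       center_year = 2006))
  ci <- quantile(fit$draws$beta_trend, c(0.025, 0.975))
  expect_lt(ci[1], -0.06)
  expect_gt(ci[2], -0.06)
  expect_true(all(fit$draws$alpha >= -10 & fit$draws$alpha <= 10))
  expect_true(all(fit$draws$nb_dispersion > 0))
})

test_that("constant counts recover their mean through the posterior", {
  counts <- data.frame(site_id = rep(paste0("s", 1:30), each = 6),
                       year = rep(2001:2006, 30), count = 5L)
  fit <- suppressWarnings(
    fit_abundance_glmm(counts, quick_mcmc(seed = 6), center_year = 2003))
  fitted_mean <- exp(fit$draws$alpha + rowMeans(fit$draws$S))
  expect_lt(abs(median(fitted_mean) - 5), 0.5)
})

test_that("dropping the detection component reproduces the census model", {
  cfg <- sim_config(n_sites = 40, years = 2001:2008, visits_per_year = 4,
                    years_per_site = NULL, protocol = "adult-count",
                    newt_p = 0.7, center_year = 2004, seed = 23)
  d <- simulate_abundance_dataset(cfg)
  counts <- aggregate_max_count(d$survey)
  f_nmix <- suppressWarnings(
    fit_nmixture(counts, quick_mcmc(seed = 8), detection = FALSE,
                 center_year = 2004))
  f_glmm <- suppressWarnings(
    fit_abundance_glmm(counts, quick_mcmc(seed = 8), center_year = 2004))
  expect_identical(f_nmix$draws$beta_trend, f_glmm$draws$beta_trend)
  expect_identical(f_nmix$draws$alpha, f_glmm$draws$alpha)
  expect_null(f_nmix$draws$det_p)
})

test_that("count-model preconditions are enforced", {
  counts <- data.frame(site_id = c("a", "b"), year = 2000, count = c(1L, 2L))
  expect_error(fit_abundance_glmm(counts, quick_mcmc()), "2 distinct years")
  counts2 <- data.frame(site_id = rep(c("a", "b"), 2),
                        year = rep(2000:2001, each = 2), count = 0L)
  w <- capture_warnings(fit_abundance_glmm(counts2, quick_mcmc(seed = 2)))
  expect_true(any(grepl("prior boundary", w)))
})

test_that("yearly abundance index reproduces direct arithmetic", {
  f <- fake_fit(alpha = rep(0, 2), beta_trend = rep(0, 2), S = rep(0, 4),
                years = 1:2, model = "nb_glmm")
  expect_equal(unclass(predict_yearly_abundance(f)), matrix(4, 2, 2),
               ignore_attr = TRUE)
  # exact log-linear identity per draw
  f2 <- fake_fit(alpha = c(1, 2), beta_trend = c(-0.1, -0.1), S = c(0.2),
                 years = c(0, 10), model = "nb_glmm")
  idx <- predict_yearly_abundance(f2)
  expect_equal(idx[, 2], idx[, 1] * exp(-1), tolerance = 1e-12)
  # hand-built draw
  f3 <- fake_fit(alpha = 0.5, beta_trend = 0.02, S = c(-0.3, 0.1),
                 years = 5, model = "nb_glmm")
  expect_equal(as.numeric(predict_yearly_abundance(f3, years = 5)),
               exp(0.5 + 0.1 - 0.3) + exp(0.5 + 0.1 + 0.1))
})

test_that("distance filter keeps the occupied neighbourhood, inclusively", {
  set.seed(12)
  n <- 40
  sites <- data.frame(site_id = paste0("s", 1:n),
                      x_coord = runif(n, 0, 10000),
                      y_coord = runif(n, 0, 10000))
  occupied <- paste0("s", 1:5)
  keep <- filter_sites_by_distance(sites, occupied, radius_m = 1500)
  # brute force double loop
  occ <- sites[sites$site_id %in% occupied, ]
  for (i in seq_len(n)) {
    dmin <- Inf
    for (j in seq_len(nrow(occ))) {
      dmin <- min(dmin, sqrt((sites$x_coord[i] - occ$x_coord[j])^2 +
                               (sites$y_coord[i] - occ$y_coord[j])^2))
    }
    expect_equal(sites$site_id[i] %in% keep, dmin <= 1500)
  }
  expect_true(all(occupied %in% keep))
  # exact boundary is retained
  tri <- data.frame(site_id = c("o", "edge", "far"),
                    x_coord = c(0, 1500, 2000), y_coord = 0)
  expect_setequal(filter_sites_by_distance(tri, "o"), c("o", "edge"))
  tri$x_coord[3] <- NA
  expect_error(filter_sites_by_distance(tri, "o"), "coordinates")
})
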