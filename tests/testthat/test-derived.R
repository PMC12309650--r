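test_that("elapsed time between periods is the gap of period midpoints", {
  p <- default_periods()
  expect_equal(elapsed_years(p$tau1, p$tau2), 8)
  expect_equal(elapsed_years(p$tau2, p$tau3), 12)
  expect_equal(elapsed_years(p$tau1, p$tau1), 0)
})

test_that("period means average the index per draw", {
  idx <- structure(matrix(c(2, 4, 6, 1, 1, 1), 2, 3, byrow = TRUE),
                   class = "yearly_index", years = 1:3, kind = "abundance",
                   n_sites = 1, include_year_effects = TRUE)
  expect_equal(period_mean(idx, period("p", 1:3)), c(4, 1))
  expect_equal(period_mean(idx, period("p", 2)), c(4, 1))
  expect_error(period_mean(idx, period("p", 4)), "not in the index")
})

test_that("proportional change tracks the trend exactly when closed-form", {
  # no trend, no year effects: ratio is one in every draw
  f <- fake_fit(alpha = rep(0.4, 50), beta_trend = rep(0, 50), S = c(0, 0.3),
                years = 2000:2009, center_year = 2000, model = "nb_glmm")
  pc <- proportional_change(predict_yearly_abundance(f))
  expect_true(all(pc$ratio == 1))
  expect_false(pc$excludes_one)
  # single site: ratio = exp(beta * span) per draw
  betas <- seq(-0.1, 0.05, length.out = 20)
  f2 <- fake_fit(alpha = rep(1, 20), beta_trend = betas, S = 0,
                 years = 2000:2009, center_year = 2000, model = "nb_glmm")
  pc2 <- proportional_change(predict_yearly_abundance(f2))
  expect_equal(pc2$ratio, exp(betas * 9), tolerance = 1e-12)
  # hand-built occupancy index
  a <- c(0.2, 0, -0.5)
  f3 <- fake_fit(alpha = a, beta_trend = c(-0.1, 0, 0.1), S = 0,
                 years = c(0, 5))
  pc3 <- proportional_change(predict_yearly_occupied(f3))
  expect_equal(pc3$ratio,
               plogis(a + c(-0.5, 0, 0.5)) / plogis(a), tolerance = 1e-12)
})

test_that("between-period decline matches elementwise brute force", {
  set.seed(42)
  n <- 1000
  m <- matrix(rlnorm(n * 6, 1, 0.4), n, 6)
  idx <- structure(m, class = "yearly_index", years = 2001:2006,
                   kind = "abundance", n_sites = 3,
                   include_year_effects = TRUE)
  pa <- period("a", 2001:2003)
  pb <- period("b", 2004:2006)
  ds <- decline_between_periods(idx, pa, pb, gl = 10)
  C_brute <- rowMeans(m[, 4:6]) / rowMeans(m[, 1:3]) - 1
  expect_equal(ds$C, C_brute, tolerance = 1e-12)
  expect_equal(ds$L, 3)
  L <- 3
  rate_brute <- -(1 - (1 - (-C_brute))^(10 / L))
  expect_equal(ds$rate, rate_brute, tolerance = 1e-12)
  expect_equal(ds$Dp, mean(C_brute < 0))
  expect_equal(ds$rate_median, median(rate_brute))
  # degenerate constant index: no change
  idx0 <- structure(matrix(2, 5, 6), class = "yearly_index",
                    years = 2001:2006, kind = "abundance", n_sites = 1,
                    include_year_effects = TRUE)
  ds0 <- decline_between_periods(idx0, pa, pb)
  expect_true(all(ds0$C == 0))
  expect_equal(ds0$Dp, 0)
  # halving means D = 0.5
  idx1 <- structure(cbind(matrix(4, 3, 3), matrix(2, 3, 3)),
                    class = "yearly_index", years = 2001:2006,
                    kind = "abundance", n_sites = 1,
                    include_year_effects = TRUE)
  ds1 <- decline_between_periods(idx1, pa, pb)
  expect_true(all(ds1$C == -0.5))
  expect_equal(ds1$Dp, 1)
})

test_that("decline probability counts negative draws, ties as non-decline", {
  expect_equal(decline_probability(c(-1, -2, -0.1)), 1)
  expect_equal(decline_probability(c(-1, 1)), 0.5)
  expect_equal(decline_probability(c(0, 0, -1, 1)), 0.25)
  set.seed(7)
  x <- rnorm(1e4)
  expect_lt(abs(decline_probability(x) - 0.5), 3 * 0.005)
  # antisymmetry when no draw is exactly zero
  set.seed(8)
  y <- rnorm(500, 0.3)
  expect_equal(decline_probability(-y), 1 - decline_probability(y))
})

test_that("annualization and window compounding are exact inverses", {
  expect_equal(annual_decline(0, 17), 0)
  expect_equal(annual_decline(0.75, 2), 0.5)
  # root-finding oracle for D = 0.5, L = 12
  v <- uniroot(function(v) (1 - v)^12 - 0.5, c(0, 1), tol = 1e-14)$root
  expect_equal(annual_decline(0.5, 12), v, tolerance = 1e-9)
  expect_equal(decline_rate(0, 10), 0)
  # closed-form cross-check: Dr = 1 - (1-D)^(GL/L)
  expect_equal(decline_rate(annual_decline(0.3, 8), 12),
               1 - 0.7^(12 / 8), tolerance = 1e-12)
  for (D in c(-1.5, -0.2, 0, 0.4, 0.95)) {
    for (L in c(1, 8, 12, 30)) {
      expect_equal(decline_rate(annual_decline(D, L), L), D,
                   tolerance = 1e-12)
    }
  }
  expect_error(annual_decline(1.2, 5), "cannot exceed")
  expect_warning(annual_decline(1, 5), "extirpation")
})

test_that("the decline rate is monotone in decline, window and elapsed time", {
  D <- seq(0.05, 0.9, by = 0.05)
  r <- decline_rate(annual_decline(D, 8), 10)
  expect_true(all(diff(r) > 0))
  gl <- 10:30
  rg <- decline_rate(annual_decline(0.4, 8), gl)
  expect_true(all(diff(rg) > 0))
  Ls <- 2:20
  rl <- vapply(Ls, function(L) decline_rate(annual_decline(0.4, L), 10),
               numeric(1))
  expect_true(all(diff(rl) < 0))
})

test_that("summaries are computed per draw, not on summaries", {
  # summarizing the yearly index first and deriving afterwards gives a
  # different answer than the per-draw computation on skewed posteriors
  set.seed(9)
  n <- 5000
  base <- rlnorm(n, 1, 0.6)
  m <- cbind(base, base, base,
             base * 0.6 + rexp(n, 2), base * 0.6 + rexp(n, 2),
             base * 0.6 + rexp(n, 2))
  idx <- structure(m, class = "yearly_index", years = 2001:2006,
                   kind = "abundance", n_sites = 1,
                   include_year_effects = TRUE)
  pa <- period("a", 2001:2003)
  pb <- period("b", 2004:2006)
  ds <- decline_between_periods(idx, pa, pb, gl = 10)
  # derived-of-summary: collapse the index to its yearly medians first
  med_year <- apply(m, 2, median)
  C_of_median <- mean(med_year[4:6]) / mean(med_year[1:3]) - 1
  rate_of_median <- -(1 - (1 - (-C_of_median))^(10 / ds$L))
  expect_gt(abs(ds$rate_median - rate_of_median), 0.005)
})

test_that("the display transform spreads high decline probabilities", {
  expect_equal(display_transform_dp(0), 0)
  expect_equal(display_transform_dp(1 - exp(-1)), 1)
  expect_equal(display_transform_dp(0.99), -log(0.01))
  expect_equal(display_transform_dp(1, n_draws = 1000), -log(1 / 1000))
  expect_error(display_transform_dp(1.2), "Dp")
})
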