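# Independent oracles and small fixtures, kept deliberately naive: plain
# loops and explicit sums, no shared code with the package internals.

# Exhaustive-enumeration likelihood for the occupancy model: sums the joint
# probability over every configuration of the latent states z across all
# site-years. Feasible only for a handful of site-years.
enum_occu_loglik <- function(params, data) {
  center <- if (is.null(params$center_year)) 0 else params$center_year
  key <- unique(data.frame(site_id = data$site_id, year = data$year))
  n_sy <- nrow(key)
  stopifnot(n_sy <= 12)
  grid <- as.matrix(expand.grid(rep(list(0:1), n_sy)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    prob <- 1
    for (m in seq_len(n_sy)) {
      z <- grid[g, m]
      lp_occ <- params$alpha +
        params$beta_trend * (key$year[m] - center) +
        params$T[[as.character(key$year[m])]] +
        params$S[[as.character(key$site_id[m])]]
      psi <- 1 / (1 + exp(-lp_occ))
      prob <- prob * ifelse(z == 1, psi, 1 - psi)
      rows <- which(data$site_id == key$site_id[m] & data$year == key$year[m])
      for (r in rows) {
        lp_det <- params$alpha_p +
          params$Sp[[as.character(data$site_id[r])]] +
          params$beta_det[1] * data$doy[r] +
          params$beta_det[2] * data$doy[r]^2 +
          params$beta_det[3] * data$minutes_after_6[r] +
          params$beta_det[4] * data$minutes_after_6[r]^2
        p <- z / (1 + exp(-lp_det))
        prob <- prob * ifelse(data$detect[r] == 1, p, 1 - p)
      }
    }
    total <- total + prob
  }
  as.numeric(log(total))
}

# Explicit truncated sum for the binomial mixture marginal, one observation.
brute_nmix_prob <- function(y, mu, size, p, K = 500) {
  total <- 0
  for (N in y:K) {
    total <- total +
      stats::dnbinom(N, mu = mu, size = size) * stats::dbinom(y, N, p)
  }
  total
}

# Random tiny occupancy dataset on natural covariate scales.
tiny_occu_data <- function(n_sites, n_years, n_visits, seed) {
  set.seed(seed)
  g <- expand.grid(site_id = paste0("s", seq_len(n_sites)),
                   year = seq_len(n_years), visit = seq_len(n_visits),
                   stringsAsFactors = FALSE)
  g <- g[order(g$site_id, g$year, g$visit), ]
  g$doy <- round(runif(nrow(g), -1, 1), 2)
  g$minutes_after_6 <- round(runif(nrow(g), -1, 1), 2)
  g$detect <- rbinom(nrow(g), 1, 0.5)
  g$count <- NA_integer_
  g$x_coord <- 0; g$y_coord <- 0
  rownames(g) <- NULL
  g
}

tiny_occu_params <- function(sites, years, alpha = 0.2, beta_trend = -0.1,
                             alpha_p = 0.3, beta_det = c(0.5, -0.3, 0.2, -0.1),
                             seed = 1) {
  set.seed(seed)
  list(alpha = alpha, beta_trend = beta_trend,
       T = stats::setNames(round(rnorm(length(years), 0, 0.3), 2),
                           as.character(years)),
       S = stats::setNames(round(rnorm(length(sites), 0, 0.5), 2), sites),
       Sp = stats::setNames(round(rnorm(length(sites), 0, 0.4), 2), sites),
       alpha_p = alpha_p, beta_det = beta_det, center_year = 0)
}

# Short fit settings used across the unit tests (not the recovery studies).
quick_mcmc <- function(seed = 1, chains = 2) {
  mcmc_config(n_chains = chains, n_iterations = 1500, n_burnin = 500,
              thin_to = 500, seed = seed)
}

# A minimal hand-built fit object for the prediction arithmetic oracles.
fake_fit <- function(alpha, beta_trend, S, years, center_year = 0,
                     model = "occupancy", sigma_T = 0.2, T_draws = NULL) {
  n <- length(alpha)
  Tm <- if (is.null(T_draws)) {
    matrix(0, n, length(years), dimnames = list(NULL, as.character(years)))
  } else {
    T_draws
  }
  Sm <- matrix(rep(S, each = n), n, length(S),
               dimnames = list(NULL, paste0("s", seq_along(S))))
  structure(
    list(model = model,
         draws = list(alpha = alpha, beta_trend = beta_trend, T = Tm,
                      S = Sm, sigma_T = rep(sigma_T, n)),
         chain = rep(1L, n), n_draws = n,
         sites = colnames(Sm), years = years, center_year = center_year),
    class = c(if (model == "occupancy") "occu_fit" else "abund_fit",
              "trend_fit"))
}
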