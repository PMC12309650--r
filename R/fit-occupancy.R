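#' Fit the Bayesian multi-year occupancy trend model
#'
#' Single-species occupancy model with imperfect detection. The ecological
#' process is `z[i,t] ~ Bernoulli(psi[i,t])` with
#' `logit(psi) = alpha + beta_trend * year_c + T_t + S_i`, where `year_c` is
#' the calendar year centered at `center_year`, `T_t` is a year random
#' effect (fluctuations around the trend) and `S_i` a site random effect.
#' The observation process is `y[i,j,t] | z ~ Bernoulli(z * p[i,j,t])` with
#' `logit(p) = alpha_p + Sp_i + b1*date + b2*date^2 + b3*hour + b4*hour^2`;
#' date (day of year) and hour (minutes after 06:00) are standardized
#' internally and the constants stored in the fit.
#'
#' Priors: slope and detection coefficients Normal(0, sd 10) (precision
#' 0.01); the occupancy intercept has the prior induced by Uniform(0,1) on
#' the probability scale (i.e. standard logistic on the logit scale);
#' random-effect standard deviations Uniform(0, 10). Sampling is by an
#' adaptive Metropolis-within-Gibbs scheme over the likelihood with the
#' latent `z` summed out, so no discrete states are sampled.
#'
#' @param data Long-format survey table (see [simulate_occupancy_dataset()]
#'   for the schema); `detect` must be 0/1.
#' @param mcmc An [mcmc_config()].
#' @param center_year Calendar year mapped to zero on the trend axis;
#'   `NULL` (default) uses the median surveyed year.
#' @param verbose Print per-chain progress.
#' @return An object of class `c("occu_fit", "trend_fit")` containing
#'   posterior draws of every parameter, chain ids, split-chain Rhat for the
#'   key parameters, and metadata (sites, years, centering, covariate
#'   standardization constants).
#' @seealso [predict_yearly_occupied()], [occupancy_marginal_loglik()]
#' @export
fit_occupancy <- function(data, mcmc = mcmc_config(), center_year = NULL,
                          verbose = FALSE) {
  validate_survey(data)
  if (anyNA(data$detect) || !all(data$detect %in% c(0L, 1L))) {
    stop("detect must be 0/1 with no missing values")
  }
  if (is.factor(data$site_id)) {
    unused <- setdiff(levels(data$site_id), unique(as.character(data$site_id)))
    if (length(unused)) {
      warning("dropping ", length(unused), " site(s) never surveyed",
              call. = FALSE)
    }
    data$site_id <- as.character(data$site_id)
  }
  years <- sort(unique(data$year))
  if (length(years) < 2) stop("need data from at least 2 distinct years")
  if (all(data$detect == 0)) {
    warning("no detections in the data; the occupancy intercept is only ",
            "weakly identified", call. = FALSE)
  }
  if (anyNA(data$doy) || anyNA(data$minutes_after_6)) {
    stop("doy and minutes_after_6 must be non-missing for occupancy fits")
  }
  sites <- sort(unique(data$site_id))
  center_year <- resolve_center_year(center_year, years)

  ord <- order(match(data$site_id, sites), data$year, data$visit)
  data <- data[ord, ]
  site_i <- match(data$site_id, sites)
  year_i <- match(data$year, years)
  sy_key <- paste(site_i, year_i)
  sy_first <- !duplicated(sy_key)
  sy_site <- site_i[sy_first]
  sy_year <- year_i[sy_first]
  obs_sy <- cumsum(sy_first)
  sy_obs_ptr <- c(0L, cumsum(tabulate(obs_sy, sum(sy_first))))
  site_obs_ptr <- c(0L, cumsum(tabulate(site_i, length(sites))))
  g <- build_groupings(sy_site, sy_year, length(sites), length(years))

  d <- std_cov(data$doy)
  h <- std_cov(data$minutes_after_6)
  Xdet <- cbind(d$z, d$z^2, h$z, h$z^2)
  standardization <- c(doy_mean = d$mean, doy_sd = d$sd,
                       minutes_mean = h$mean, minutes_sd = h$sd)

  naive_occ <- clamp(mean(tapply(data$detect, sy_key, max)), 0.05, 0.95)
  sy_max <- tapply(data$detect, obs_sy, max)
  det_rate <- data$detect[sy_max[as.character(obs_sy)] == 1]
  naive_p <- clamp(if (length(det_rate)) mean(det_rate) else 0.5, 0.05, 0.95)
  init0 <- list(alpha = stats::qlogis(naive_occ), beta_trend = 0,
                alpha_p = stats::qlogis(naive_p), beta_det = rep(0, 4),
                T = rep(0, length(years)), S = rep(0, length(sites)),
                Sp = rep(0, length(sites)),
                sigma_T = 0.5, sigma_S = 0.5, sigma_Sp = 0.5)

  set.seed(mcmc$seed)
  chains <- vector("list", mcmc$n_chains)
  for (c in seq_len(mcmc$n_chains)) {
    init <- jitter_init(init0, list(alpha = 0.5, beta_trend = 0.02,
                                    alpha_p = 0.5))
    init$sigma_T <- stats::runif(1, 0.2, 1)
    init$sigma_S <- stats::runif(1, 0.2, 1)
    init$sigma_Sp <- stats::runif(1, 0.2, 1)
    t0 <- Sys.time()
    chains[[c]] <- occu_mcmc_cpp(
      y = as.integer(data$detect), sy_obs_ptr = as.integer(sy_obs_ptr),
      obs_site = as.integer(site_i - 1L), Xdet = Xdet,
      sy_site = as.integer(sy_site - 1L), sy_year = as.integer(sy_year - 1L),
      sy_yearc = as.numeric(years[sy_year] - center_year),
      site_sy_ptr = g$site_sy_ptr, year_sy_idx = g$year_sy_idx,
      year_sy_ptr = g$year_sy_ptr, site_obs_ptr = as.integer(site_obs_ptr),
      n_sites = length(sites), n_years = length(years),
      n_burnin = mcmc$n_burnin, n_thin = mcmc$thin, n_keep = mcmc$n_keep,
      init = init)
    if (verbose) {
      message(sprintf("chain %d done in %.1f s", c,
                      as.numeric(Sys.time() - t0, units = "secs")))
    }
  }
  fit <- new_trend_fit("occu_fit", "occupancy", chains, mcmc, sites, years,
                       center_year,
                       extra = list(standardization = standardization,
                                    n_obs = nrow(data)))
  fit$rhat <- fit_rhat(fit$draws, fit$chain,
                       c("alpha", "beta_trend", "alpha_p",
                         "sigma_T", "sigma_S", "sigma_Sp"))
  warn_if_unconverged(fit)
}

#' Marginal log-likelihood of the occupancy model
#'
#' Evaluates the likelihood with the latent occupancy state summed out:
#' each site-year contributes
#' `psi * prod_j p^y (1-p)^(1-y) + (1 - psi) * 1{all y = 0}`.
#' Covariates (`doy`, `minutes_after_6`) are used exactly as supplied; pass
#' standardized columns if `params` is on the standardized scale.
#'
#' @param params List with elements `alpha`, `beta_trend`, `T` (named by
#'   calendar year), `S` and `Sp` (named by `site_id`), `alpha_p`,
#'   `beta_det` (length 4: date, date^2, hour, hour^2) and optionally
#'   `center_year` (default 0).
#' @param data Survey table with at least `site_id, year, visit, doy,
#'   minutes_after_6, detect`.
#' @return The total log-likelihood (finite scalar, or `-Inf` for data
#'   impossible under `params`).
#' @export
occupancy_marginal_loglik <- function(params, data) {
  if (anyNA(data$doy) || anyNA(data$minutes_after_6)) {
    stop("covariates contain missing values")
  }
  center <- if (is.null(params$center_year)) 0 else params$center_year
  Tt <- params$T[as.character(data$year)]
  if (anyNA(Tt)) stop("params$T must be named by every year in the data")
  S <- params$S[as.character(data$site_id)]
  Sp <- params$Sp[as.character(data$site_id)]
  if (anyNA(S) || anyNA(Sp)) {
    stop("params$S and params$Sp must be named by every site in the data")
  }
  b <- params$beta_det
  lp_det <- params$alpha_p + Sp + b[1] * data$doy + b[2] * data$doy^2 +
    b[3] * data$minutes_after_6 + b[4] * data$minutes_after_6^2
  if (anyNA(lp_det)) stop("covariates contain missing values")
  log_p <- stats::plogis(lp_det, log.p = TRUE)
  log_q <- stats::plogis(-lp_det, log.p = TRUE)
  bern <- ifelse(data$detect == 1, log_p, log_q)

  key <- paste(data$site_id, data$year)
  A <- tapply(bern, key, sum)
  allzero <- tapply(data$detect, key, max) == 0
  first <- !duplicated(key)
  lp_occ <- params$alpha + params$beta_trend * (data$year[first] - center) +
    Tt[first] + S[first]
  psi <- stats::plogis(lp_occ)
  A <- A[key[first]]
  allzero <- allzero[key[first]]
  contrib <- ifelse(allzero,
                    log(psi * exp(A) + (1 - psi)),
                    log(psi) + A)
  sum(contrib)
}

#' Posterior yearly number of occupied sites
#'
#' For each posterior draw and each requested year, sums the occupancy
#' probability over all fitted sites:
#' `sum_i logistic(alpha + beta_trend * year_c [+ T_t] + S_i)`. With
#' `include_year_effects = FALSE` the index tracks the smooth trend only
#' (random yearly fluctuations excluded), which is the convention for
#' study-period endpoints; with `TRUE` the year effects are included, the
#' convention for period averages. Year effects for years the model never
#' saw are drawn from their prior `Normal(0, sigma_T)` per draw.
#'
#' @param fit An `occu_fit`.
#' @param years Calendar years to evaluate (default: fitted years).
#' @param include_year_effects Include the year random effect `T_t`?
#' @param extrapolate Allow years outside the fitted range.
#' @param seed Optional seed for prior draws of `T_t` in unfitted years.
#' @return A `yearly_index` object: a draws x years matrix with attributes
#'   `years`, `kind` and `n_sites`.
#' @export
predict_yearly_occupied <- function(fit, years = fit$years,
                                    include_year_effects = FALSE,
                                    extrapolate = FALSE, seed = NULL) {
  stopifnot(inherits(fit, "occu_fit"))
  yearly_index_engine(fit, years, include_year_effects, extrapolate, seed,
                      transform = stats::plogis, kind = "occupancy")
}

yearly_index_engine <- function(fit, years, include_year_effects,
                                extrapolate, seed, transform, kind) {
  if (!extrapolate &&
      (min(years) < min(fit$years) || max(years) > max(fit$years))) {
    stop("requested years outside the fitted range; ",
         "set extrapolate = TRUE to force")
  }
  dr <- fit$draws
  n <- fit$n_draws
  S <- dr$S
  out <- matrix(0, n, length(years))
  if (!is.null(seed)) set.seed(seed)
  for (j in seq_along(years)) {
    yc <- years[j] - fit$center_year
    lp <- dr$alpha + dr$beta_trend * yc
    if (include_year_effects) {
      k <- match(as.character(years[j]), colnames(dr$T))
      lp <- lp + if (!is.na(k)) dr$T[, k] else stats::rnorm(n, 0, dr$sigma_T)
    }
    out[, j] <- rowSums(transform(lp + S))
  }
  structure(out, class = "yearly_index", years = years, kind = kind,
            n_sites = ncol(S),
            include_year_effects = include_year_effects)
}

#' @export
print.yearly_index <- function(x, ...) {
  cat(sprintf("Yearly %s index: %d draws x %d years over %d sites (%s)\n",
              attr(x, "kind"), nrow(x), ncol(x), attr(x, "n_sites"),
              if (attr(x, "include_year_effects")) {
                "with year effects"
              } else {
                "trend only"
              }))
  q <- apply(unclass(x), 2, stats::quantile, c(0.025, 0.5, 0.975))
  colnames(q) <- attr(x, "years")
  print(round(q, 2))
  invisible(x)
}
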