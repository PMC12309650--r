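#' Collapse repeated counts to one seasonal maximum per site-year
#'
#' Repeated within-season counts are reduced to the highest count per site
#' and year, the standard index for breeding-season surveys where within-year
#' replicates are not independent samples of the same closed population.
#' All-zero site-years are retained as observed zeros.
#'
#' @param survey Long-format survey table with a `count` column.
#' @return A data frame with one row per site-year: `site_id, year, count`
#'   (the maximum), `n_visits`, and site coordinates.
#' @export
aggregate_max_count <- function(survey) {
  validate_survey(survey)
  if (anyNA(survey$count)) stop("count contains missing values")
  if (any(survey$count < 0)) stop("counts must be non-negative")
  key <- paste(survey$site_id, survey$year, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(
    site_id = survey$site_id[first],
    year = survey$year[first],
    count = as.integer(tapply(survey$count, key, max)[key[first]]),
    n_visits = as.integer(tapply(survey$count, key, length)[key[first]]),
    x_coord = survey$x_coord[first],
    y_coord = survey$y_coord[first])
  rownames(out) <- NULL
  out[order(out$site_id, out$year), ]
}

validate_counts <- function(counts) {
  need <- c("site_id", "year", "count")
  miss <- setdiff(need, names(counts))
  if (length(miss)) {
    stop("count table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (anyNA(counts$count)) stop("count contains missing values")
  if (any(counts$count < 0)) stop("counts must be non-negative")
  invisible(counts)
}

# Shared driver for the two count models.
fit_count_model <- function(counts, mcmc, center_year, detection, model,
                            subclass, verbose) {
  validate_counts(counts)
  years <- sort(unique(counts$year))
  if (length(years) < 2) stop("need counts from at least 2 distinct years")
  if (all(counts$count == 0)) {
    warning("all counts are zero; the abundance intercept is only ",
            "identified at the prior boundary", call. = FALSE)
  }
  sites <- sort(unique(counts$site_id))
  center_year <- resolve_center_year(center_year, years)
  ord <- order(match(counts$site_id, sites), counts$year)
  counts <- counts[ord, ]
  sy_site <- match(counts$site_id, sites)
  sy_year <- match(counts$year, years)
  g <- build_groupings(sy_site, sy_year, length(sites), length(years))

  init0 <- list(alpha = clamp(log(mean(counts$count) + 0.5), -9, 9),
                beta_trend = 0, T = rep(0, length(years)),
                S = rep(0, length(sites)), sigma_T = 0.5, sigma_S = 0.5,
                nb_dispersion = 1, det_p = 0.7)
  set.seed(mcmc$seed)
  chains <- vector("list", mcmc$n_chains)
  for (c in seq_len(mcmc$n_chains)) {
    init <- jitter_init(init0, list(alpha = 0.3, beta_trend = 0.02))
    init$alpha <- clamp(init$alpha, -9.5, 9.5)
    init$sigma_T <- stats::runif(1, 0.2, 1)
    init$sigma_S <- stats::runif(1, 0.2, 1)
    init$nb_dispersion <- stats::runif(1, 0.5, 3)
    init$det_p <- stats::runif(1, 0.4, 0.95)
    t0 <- Sys.time()
    chains[[c]] <- count_mcmc_cpp(
      y = as.integer(counts$count),
      sy_site = as.integer(sy_site - 1L), sy_year = as.integer(sy_year - 1L),
      sy_yearc = as.numeric(years[sy_year] - center_year),
      site_sy_ptr = g$site_sy_ptr, year_sy_idx = g$year_sy_idx,
      year_sy_ptr = g$year_sy_ptr,
      n_sites = length(sites), n_years = length(years),
      detection = detection,
      n_burnin = mcmc$n_burnin, n_thin = mcmc$thin, n_keep = mcmc$n_keep,
      init = init)
    if (verbose) {
      message(sprintf("chain %d done in %.1f s", c,
                      as.numeric(Sys.time() - t0, units = "secs")))
    }
  }
  fit <- new_trend_fit(subclass, model, chains, mcmc, sites, years,
                       center_year, extra = list(detection = detection))
  if (!detection) fit$draws$det_p <- NULL
  fit$rhat <- fit_rhat(fit$draws, fit$chain,
                       intersect(c("alpha", "beta_trend", "sigma_T",
                                   "sigma_S", "nb_dispersion", "det_p"),
                                 names(fit$draws)))
  warn_if_unconverged(fit)
}

#' Fit the negative-binomial abundance trend model (count census)
#'
#' Generalized linear mixed model for counts treated as a census of the
#' quantity of interest (e.g. egg-clutch counts whose detection probability
#' exceeds 90%): `N[i,t] ~ NegBin(mu, size)` with
#' `log(mu) = alpha + beta_trend * year_c + T_t + S_i` and the observed
#' count equal to `N`. The negative binomial is parameterized by mean and
#' size (variance `mu + mu^2/size`). Priors: `alpha ~ Uniform(-10, 10)`,
#' `beta_trend ~ Normal(0, sd 10)`, RE standard deviations Uniform(0, 10),
#' size Uniform(0, 50).
#'
#' @param counts Site-year count table (see [aggregate_max_count()]).
#' @inheritParams fit_occupancy
#' @return An object of class `c("abund_fit", "trend_fit")`.
#' @export
fit_abundance_glmm <- function(counts, mcmc = mcmc_config(),
                               center_year = NULL, verbose = FALSE) {
  fit_count_model(counts, mcmc, center_year, detection = FALSE,
                  model = "nb_glmm", subclass = "abund_fit",
                  verbose = verbose)
}

#' Fit the binomial mixture model for seasonal maximum counts
#'
#' Binomial N-mixture model with negative-binomial latent abundance for one
#' (maximum) count per site and season: `N[i,t] ~ NegBin(mu, size)` as in
#' [fit_abundance_glmm()], and `y[i,t] | N ~ Binomial(N, det_p)` with a
#' single detection probability `det_p ~ Uniform(0, 1)`. The latent `N` is
#' marginalized in closed form (binomial thinning of a negative binomial is
#' again negative binomial with mean `det_p * mu`), so the sampler never
#' visits the latent counts. With one count per season, `det_p` is informed
#' almost entirely by its prior (it is confounded with the intercept); the
#' trend remains identified, and `detection = FALSE` drops the detection
#' layer entirely, reproducing the census model.
#'
#' @inheritParams fit_abundance_glmm
#' @param detection Keep the binomial detection component? `FALSE` collapses
#'   the model to [fit_abundance_glmm()].
#' @return An object of class `c("nmix_fit", "trend_fit")`.
#' @seealso [nmixture_marginal_loglik()]
#' @export
fit_nmixture <- function(counts, mcmc = mcmc_config(), detection = TRUE,
                         center_year = NULL, verbose = FALSE) {
  fit_count_model(counts, mcmc, center_year, detection = detection,
                  model = "nmixture", subclass = "nmix_fit",
                  verbose = verbose)
}

#' Marginal log-likelihood of the binomial mixture model
#'
#' Evaluates `P(y) = sum_{N >= y} NegBin(N; mu, size) * Binomial(y; N, p)`
#' by explicit truncated summation. The truncation bound is chosen
#' adaptively per site-year as the larger of three times the maximum
#' observed count and the `1 - 1e-8` quantile of the negative binomial, so
#' the neglected tail mass is below `1e-8`.
#'
#' @param params List with `alpha`, `beta_trend`, `T` (named by year), `S`
#'   (named by site), `nb_dispersion`, `det_p`, optional `center_year`
#'   (default 0).
#' @param counts Site-year count table.
#' @param K Optional fixed truncation bound; must be at least the maximum
#'   observed count.
#' @return Total log-likelihood over the table rows.
#' @export
nmixture_marginal_loglik <- function(params, counts, K = NULL) {
  validate_counts(counts)
  if (!is.null(K) && K < max(counts$count)) {
    stop("K must be at least the maximum observed count")
  }
  center <- if (is.null(params$center_year)) 0 else params$center_year
  Tt <- params$T[as.character(counts$year)]
  S <- params$S[as.character(counts$site_id)]
  if (anyNA(Tt) || anyNA(S)) {
    stop("params$T and params$S must be named by every year/site in counts")
  }
  mu <- exp(params$alpha + params$beta_trend * (counts$year - center) +
              Tt + S)
  size <- params$nb_dispersion
  p <- params$det_p
  ll <- vapply(seq_len(nrow(counts)), function(r) {
    y <- counts$count[r]
    Kr <- if (is.null(K)) {
      max(3 * max(counts$count), stats::qnbinom(1 - 1e-8, mu = mu[r],
                                                size = size), y)
    } else {
      K
    }
    N <- y:Kr
    log(sum(stats::dnbinom(N, mu = mu[r], size = size) *
              stats::dbinom(y, N, p)))
  }, numeric(1))
  sum(ll)
}

#' Posterior yearly total abundance across sites
#'
#' Per draw and year, `sum_i exp(alpha + beta_trend * year_c [+ T_t] + S_i)`
#' — the expected total abundance over the fitted sites (the detection layer
#' does not enter: the index is latent abundance, not expected counts).
#' Conventions for `include_year_effects` and unfitted years are as in
#' [predict_yearly_occupied()].
#'
#' @param fit An `abund_fit` or `nmix_fit`.
#' @inheritParams predict_yearly_occupied
#' @return A `yearly_index` object.
#' @export
predict_yearly_abundance <- function(fit, years = fit$years,
                                     include_year_effects = FALSE,
                                     extrapolate = FALSE, seed = NULL) {
  stopifnot(inherits(fit, "trend_fit"),
            fit$model %in% c("nb_glmm", "nmixture"))
  yearly_index_engine(fit, years, include_year_effects, extrapolate, seed,
                      transform = exp, kind = "abundance")
}

#' Restrict sites to the dispersal neighbourhood of occupied sites
#'
#' Keeps every site within `radius_m` (inclusive) of a site that was
#' occupied at least once, dropping areas the species could never have
#' reached by dispersal; the default radius of 1500 m is a typical maximum
#' amphibian dispersal distance. Ever-occupied sites are always retained
#' (distance zero to themselves).
#'
#' @param sites Data frame with `site_id`, `x_coord`, `y_coord` (planar
#'   meters); a survey table works (first row per site is used).
#' @param occupied_site_ids Sites with at least one detection over the
#'   study.
#' @param radius_m Retention radius in meters.
#' @return Character vector of retained site ids.
#' @export
filter_sites_by_distance <- function(sites, occupied_site_ids,
                                     radius_m = 1500) {
  first <- !duplicated(sites$site_id)
  s <- sites[first, c("site_id", "x_coord", "y_coord")]
  if (anyNA(s$x_coord) || anyNA(s$y_coord)) {
    stop("missing coordinates for some sites")
  }
  occ <- s[s$site_id %in% occupied_site_ids, ]
  if (nrow(occ) == 0) stop("no occupied sites among the supplied sites")
  dx <- outer(s$x_coord, occ$x_coord, "-")
  dy <- outer(s$y_coord, occ$y_coord, "-")
  mind <- sqrt(apply(dx^2 + dy^2, 1, min))
  sort(s$site_id[mind <= radius_m])
}
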