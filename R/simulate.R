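# Synthetic survey data with known truth.
#
# The generator draws the sampling design first (which years each site is
# visited in, how many visits, visit dates/times, site coordinates), then the
# latent states, then the observations. All randomness flows from the seed in
# the configuration so that a configuration identifies a dataset.

# sample() treats a scalar first argument as 1:x; this never does
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# Draw the site x year x visit skeleton shared by all generators.
sim_design <- function(cfg) {
  sites <- sprintf("site_%03d", seq_len(cfg$n_sites))
  x <- stats::runif(cfg$n_sites, 0, 30000)
  y <- stats::runif(cfg$n_sites, 0, 30000)
  site_years <- lapply(seq_len(cfg$n_sites), function(i) {
    if (is.null(cfg$years_per_site)) return(cfg$years)
    k <- resample(seq(cfg$years_per_site[1], cfg$years_per_site[2]), 1)
    sort(resample(cfg$years, k))
  })
  sy <- data.frame(
    site_id = rep(sites, lengths(site_years)),
    site = rep(seq_len(cfg$n_sites), lengths(site_years)),
    year = unlist(site_years))
  nv <- if (cfg$visits_per_year[1] == cfg$visits_per_year[2]) {
    rep(cfg$visits_per_year[1], nrow(sy))
  } else {
    resample(seq(cfg$visits_per_year[1], cfg$visits_per_year[2]),
             nrow(sy), replace = TRUE)
  }
  obs <- sy[rep(seq_len(nrow(sy)), nv), ]
  obs$visit <- unlist(lapply(nv, seq_len))
  obs$sy <- rep(seq_len(nrow(sy)), nv)
  obs$doy <- resample(seq(cfg$doy_range[1], cfg$doy_range[2]),
                      nrow(obs), replace = TRUE)
  obs$minutes_after_6 <- round(stats::runif(nrow(obs), cfg$minutes_range[1],
                                            cfg$minutes_range[2]))
  rownames(obs) <- NULL
  list(sites = sites, x = x, y = y, sy = sy, obs = obs)
}

# Standardize a covariate, guarding degenerate (constant) draws.
std_cov <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) s <- 1
  list(z = (v - mean(v)) / s, mean = mean(v), sd = s)
}

# Latent linear predictor for site-years: alpha + beta * yearc + T_t + S_i.
sy_linpred <- function(sy, alpha, beta, Tt, Si, years, center_year) {
  yearc <- sy$year - center_year
  alpha + beta * yearc + Tt[match(sy$year, years)] + Si[sy$site]
}

# Visit-level detection probability from the date/hour quadratic.
visit_det_prob <- function(obs, cfg, Sp) {
  d <- std_cov(obs$doy)
  h <- std_cov(obs$minutes_after_6)
  dp <- cfg$det_params
  lp <- dp[1] + Sp[obs$site] + dp[2] * d$z + dp[3] * d$z^2 +
    dp[4] * h$z + dp[5] * h$z^2
  list(p = stats::plogis(lp),
       standardization = c(doy_mean = d$mean, doy_sd = d$sd,
                           minutes_mean = h$mean, minutes_sd = h$sd))
}

finish_survey <- function(obs, design) {
  data.frame(site_id = obs$site_id, year = obs$year, visit = obs$visit,
             doy = obs$doy, minutes_after_6 = obs$minutes_after_6,
             detect = obs$detect, count = obs$count,
             x_coord = design$x[obs$site], y_coord = design$y[obs$site])
}

#' Simulate a multi-season detection/non-detection dataset
#'
#' Generates latent occupancy states `z` from the logit-linear trend model
#' with year and site random effects, then per-visit detections from the
#' date/hour detection quadratic (covariates standardized internally; the
#' constants are returned with the truth).
#'
#' @param config A [sim_config()].
#' @return A list with `survey` (long-format data frame: one row per
#'   site x year x visit with columns `site_id, year, visit, doy,
#'   minutes_after_6, detect, count, x_coord, y_coord`) and `truth` (latent
#'   states, random effects, detection probabilities and standardization
#'   constants).
#' @export
simulate_occupancy_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  design <- sim_design(config)
  Si <- stats::rnorm(config$n_sites, 0, config$sigma_site)
  Tt <- stats::rnorm(length(config$years), 0, config$sigma_year)
  Sp <- stats::rnorm(config$n_sites, 0, config$sigma_site_det)
  psi <- stats::plogis(sy_linpred(design$sy, config$alpha_occ,
                                  config$beta_trend, Tt, Si,
                                  config$years, config$center_year))
  z <- stats::rbinom(nrow(design$sy), 1, psi)
  det <- visit_det_prob(design$obs, config, Sp)
  obs <- design$obs
  obs$detect <- stats::rbinom(nrow(obs), 1, z[obs$sy] * det$p)
  obs$count <- NA_integer_
  truth <- list(
    site_year = data.frame(site_id = design$sy$site_id,
                           year = design$sy$year, psi = psi, z = z),
    S = Si, T = Tt, Sp = Sp, p = det$p,
    standardization = det$standardization, config = config)
  list(survey = finish_survey(obs, design), truth = truth)
}

#' Simulate a multi-season count dataset
#'
#' Latent abundance per site-year is negative binomial around a log-linear
#' trend with year and site random effects. Under the `"clutch-count"`
#' protocol the generator emits one count per site-year equal to the true
#' abundance (clutch counts are treated as a census: their detectability
#' exceeds 90%). Under the `"adult-count"` protocol each visit records a
#' binomial count of the true abundance with per-individual detection
#' probability `newt_p`.
#'
#' @inheritParams simulate_occupancy_dataset
#' @return As [simulate_occupancy_dataset()]; `truth$site_year` carries the
#'   true abundance `N`.
#' @export
simulate_abundance_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  stopifnot("nb_dispersion must be > 0" = config$nb_dispersion > 0)
  set.seed(config$seed)
  design <- sim_design(config)
  Si <- stats::rnorm(config$n_sites, 0, config$sigma_site)
  Tt <- stats::rnorm(length(config$years), 0, config$sigma_year)
  mu <- exp(sy_linpred(design$sy, config$alpha_abund, config$beta_trend,
                       Tt, Si, config$years, config$center_year))
  N <- stats::rnbinom(nrow(design$sy), mu = mu, size = config$nb_dispersion)
  if (config$protocol == "clutch-count") {
    obs <- design$sy
    obs$visit <- 1L
    obs$sy <- seq_len(nrow(design$sy))
    obs$doy <- NA_integer_
    obs$minutes_after_6 <- NA_real_
    obs$count <- N
  } else {
    obs <- design$obs
    obs$count <- stats::rbinom(nrow(obs), N[obs$sy], config$newt_p)
  }
  obs$detect <- as.integer(obs$count > 0)
  truth <- list(
    site_year = data.frame(site_id = design$sy$site_id,
                           year = design$sy$year, mu = mu, N = N),
    S = Si, T = Tt, config = config)
  list(survey = finish_survey(obs, design), truth = truth)
}

#' Simulate coupled occupancy and abundance data from one latent population
#'
#' In the coupled scenario the occupancy state is a deterministic function
#' of latent abundance, `z = 1\{N > 0\}`: a site stays "occupied" while any
#' individuals remain, so a declining population loses abundance faster
#' (proportionally) than it loses occupied sites. This reproduces the
#' classic expectation that presence-absence monitoring detects a decline
#' later and less steeply than counts do.
#'
#' @inheritParams simulate_occupancy_dataset
#' @return A list with `occupancy` and `abundance` survey tables sharing the
#'   same design and latent population, plus `truth`.
#' @export
simulate_coupled_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  design <- sim_design(config)
  Si <- stats::rnorm(config$n_sites, 0, config$sigma_site)
  Tt <- stats::rnorm(length(config$years), 0, config$sigma_year)
  Sp <- stats::rnorm(config$n_sites, 0, config$sigma_site_det)
  mu <- exp(sy_linpred(design$sy, config$alpha_abund, config$beta_trend,
                       Tt, Si, config$years, config$center_year))
  N <- stats::rnbinom(nrow(design$sy), mu = mu, size = config$nb_dispersion)
  z <- as.integer(N > 0)
  det <- visit_det_prob(design$obs, config, Sp)
  occ <- design$obs
  occ$detect <- stats::rbinom(nrow(occ), 1, z[occ$sy] * det$p)
  occ$count <- NA_integer_
  ab <- design$obs
  if (config$protocol == "clutch-count") {
    ab <- design$sy
    ab$visit <- 1L
    ab$sy <- seq_len(nrow(design$sy))
    ab$doy <- NA_integer_
    ab$minutes_after_6 <- NA_real_
    ab$count <- N
  } else {
    ab$count <- stats::rbinom(nrow(ab), N[ab$sy], config$newt_p)
  }
  ab$detect <- as.integer(ab$count > 0)
  truth <- list(
    site_year = data.frame(site_id = design$sy$site_id,
                           year = design$sy$year, mu = mu, N = N, z = z),
    S = Si, T = Tt, Sp = Sp,
    standardization = det$standardization, config = config)
  list(occupancy = finish_survey(occ, design),
       abundance = finish_survey(ab, design), truth = truth)
}

#' Read and write long-format survey tables
#'
#' The on-disk format is a plain CSV with header
#' `site_id,year,visit,doy,minutes_after_6,detect,count,x_coord,y_coord`.
#'
#' @param survey A survey data frame.
#' @param path File path.
#' @return `read_survey_csv` returns the validated data frame;
#'   `write_survey_csv` returns `path` invisibly.
#' @export
write_survey_csv <- function(survey, path) {
  validate_survey(survey)
  utils::write.csv(survey, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_survey(x)
  x
}

validate_survey <- function(x) {
  need <- c("site_id", "year", "visit", "doy", "minutes_after_6",
            "detect", "count", "x_coord", "y_coord")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("survey table is missing columns: ", paste(miss, collapse = ", "))
  }
  invisible(x)
}
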