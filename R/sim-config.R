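#' Configuration for the synthetic monitoring-data generator
#'
#' Bundles every quantity that defines a simulated multi-season amphibian
#' monitoring programme: the sampling design (sites, years, visits), the
#' occupancy and abundance trend processes, random-effect scales, the
#' date/hour detection quadratic, and the count protocol. The defaults
#' emulate a long-term wetland-monitoring study: 212 breeding sites followed
#' over a 27-year window with a five-year gap, each site sampled in 2--9
#' years, up to 8 visits per sampled year during a February--June breeding
#' window, with day and night surveys.
#'
#' @param n_sites Number of monitored sites (positive integer).
#' @param years Ordered vector of calendar years; gaps are allowed and the
#'   default omits 2012--2016.
#' @param visits_per_year Either a single integer (fixed number of visits) or
#'   a length-2 range from which each site-year's visit count is drawn
#'   uniformly. Must lie in 1..8.
#' @param years_per_site Either `NULL` for a full panel (every site sampled
#'   every year) or a length-2 range for the number of distinct years in
#'   which each site is sampled.
#' @param alpha_occ Occupancy intercept on the logit scale (average
#'   occupancy in the centering year at an average site).
#' @param alpha_abund Abundance intercept on the log scale.
#' @param beta_trend Per-year trend slope (logit scale for occupancy, log
#'   scale for abundance).
#' @param sigma_site,sigma_year Standard deviations (>= 0) of the site and
#'   year random effects shared by both processes.
#' @param sigma_site_det Standard deviation of the site-level detection
#'   random effect.
#' @param det_params Named or positional numeric vector
#'   `(alpha_p, b_date, b_date2, b_hour, b_hour2)`: intercept and
#'   linear/quadratic coefficients of the detection model, applied to
#'   internally standardized day-of-year and minutes-after-06:00.
#' @param nb_dispersion Negative-binomial size parameter (> 0); variance is
#'   `mu + mu^2 / size`.
#' @param newt_p Per-visit individual detection probability in (0, 1], used
#'   by the `"adult-count"` protocol.
#' @param protocol `"adult-count"` (per-visit binomial counts of adults, as
#'   for newts) or `"clutch-count"` (one near-census count per site-year, as
#'   for brown-frog egg clutches whose detectability exceeds 90%).
#' @param doy_range Day-of-year window for visits (default 32--181,
#'   February--June).
#' @param minutes_range Visit time window in minutes after 06:00 (default
#'   0--1080, i.e. 06:00 to midnight: surveys run by day and by night).
#' @param center_year Calendar year mapped to zero on the trend axis.
#' @param coupled If `TRUE`, occupancy truth is derived from abundance truth
#'   as `z = 1\{N > 0\}` instead of being an independent process.
#' @param seed Integer seed; identical configurations reproduce identical
#'   datasets bit for bit.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_occupancy_dataset()], [simulate_abundance_dataset()],
#'   [simulate_coupled_dataset()]
#' @export
sim_config <- function(n_sites = 212L,
                       years = c(1996:2011, 2017:2022),
                       visits_per_year = c(2L, 8L),
                       years_per_site = c(2L, 9L),
                       alpha_occ = 0.5,
                       alpha_abund = log(10),
                       beta_trend = -0.05,
                       sigma_site = 1,
                       sigma_year = 0.3,
                       sigma_site_det = 0.5,
                       det_params = c(alpha_p = 0.5, b_date = 0.3,
                                      b_date2 = -0.4, b_hour = 0.2,
                                      b_hour2 = -0.3),
                       nb_dispersion = 1.5,
                       newt_p = 0.6,
                       protocol = c("adult-count", "clutch-count"),
                       doy_range = c(32L, 181L),
                       minutes_range = c(0, 1080),
                       center_year = 2009,
                       coupled = FALSE,
                       seed = 1L) {
  protocol <- match.arg(protocol)
  stopifnot(
    "n_sites must be a positive integer" =
      is.numeric(n_sites) && length(n_sites) == 1 && n_sites >= 1,
    "years must be non-empty" = length(years) >= 1,
    "years must be strictly increasing" =
      length(years) == 1 || all(diff(years) > 0),
    "sigma_site must be >= 0" = sigma_site >= 0,
    "sigma_year must be >= 0" = sigma_year >= 0,
    "sigma_site_det must be >= 0" = sigma_site_det >= 0,
    "nb_dispersion must be > 0" = nb_dispersion > 0,
    "newt_p must be in (0, 1]" = newt_p > 0 && newt_p <= 1,
    "det_params must have 5 elements" = length(det_params) == 5,
    "seed must be a single integer" = is.numeric(seed) && length(seed) == 1
  )
  if (length(visits_per_year) == 1) {
    visits_per_year <- rep(as.integer(visits_per_year), 2)
  }
  stopifnot(
    "visits_per_year must lie in 1..8" =
      visits_per_year[1] >= 1 && visits_per_year[2] <= 8 &&
      visits_per_year[1] <= visits_per_year[2]
  )
  if (!is.null(years_per_site)) {
    if (length(years_per_site) == 1) years_per_site <- rep(years_per_site, 2)
    years_per_site <- pmin(as.integer(years_per_site), length(years))
  }
  det_params <- as.numeric(det_params)
  names(det_params) <- c("alpha_p", "b_date", "b_date2", "b_hour", "b_hour2")
  structure(
    list(n_sites = as.integer(n_sites), years = as.integer(years),
         visits_per_year = as.integer(visits_per_year),
         years_per_site = years_per_site,
         alpha_occ = alpha_occ, alpha_abund = alpha_abund,
         beta_trend = beta_trend,
         sigma_site = sigma_site, sigma_year = sigma_year,
         sigma_site_det = sigma_site_det,
         det_params = det_params, nb_dispersion = nb_dispersion,
         newt_p = newt_p, protocol = protocol,
         doy_range = doy_range, minutes_range = minutes_range,
         center_year = center_year, coupled = coupled,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic monitoring design\n")
  cat(sprintf("  %d sites, %d candidate years (%d-%d), visits %d-%d\n",
              x$n_sites, length(x$years), min(x$years), max(x$years),
              x$visits_per_year[1], x$visits_per_year[2]))
  if (is.null(x$years_per_site)) {
    cat("  full panel (every site sampled every year)\n")
  } else {
    cat(sprintf("  each site sampled in %d-%d years\n",
                x$years_per_site[1], x$years_per_site[2]))
  }
  cat(sprintf("  occupancy: alpha = %.3g, abundance: alpha = %.3g, trend = %.3g/yr\n",
              x$alpha_occ, x$alpha_abund, x$beta_trend))
  cat(sprintf("  RE sd: site %.3g, year %.3g; NB size %.3g; protocol %s; seed %d\n",
              x$sigma_site, x$sigma_year, x$nb_dispersion, x$protocol, x$seed))
  invisible(x)
}
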