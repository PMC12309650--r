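# Orchestration: simulate (or ingest) -> fit -> derive -> assess, with
# convergence gating and a reproducibility manifest.

#' Configuration for a full occupancy-vs-abundance assessment run
#'
#' @param sim A [sim_config()] used to generate coupled synthetic data, or
#'   `NULL` if `occupancy_data`/`abundance_data` are supplied.
#' @param occupancy_data,abundance_data Survey tables (data frames or CSV
#'   paths); ignored when `sim` is given.
#' @param mcmc An [mcmc_config()].
#' @param periods List of [period()] objects in chronological order;
#'   consecutive pairs are assessed.
#' @param gl Assessment window in years (longest of 10 years and 3
#'   generation lengths for the species).
#' @param detection Keep the detection component in the count model
#'   (binomial mixture)? `FALSE` uses the census (GLMM) model.
#' @param species Label used in the report.
#' @param out_dir Directory for artifacts (draws, summaries, report,
#'   manifest); `NULL` writes nothing.
#' @param distance_filter_m Radius for the occupied-neighbourhood site
#'   filter applied to the count data; `NULL` disables it.
#' @param rhat_threshold Convergence gate on the key parameters.
#' @param force Proceed past a failed convergence gate.
#' @param seed Root seed for every stochastic stage.
#' @param verbose Log stage progress to stderr.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), occupancy_data = NULL,
                       abundance_data = NULL, mcmc = mcmc_config(),
                       periods = default_periods(), gl = 10,
                       detection = TRUE, species = "synthetic_species",
                       out_dir = NULL, distance_filter_m = 1500,
                       rhat_threshold = 1.1, force = FALSE, seed = 1L,
                       verbose = FALSE) {
  stopifnot(length(periods) >= 2, gl >= 10)
  if (is.null(sim) && (is.null(occupancy_data) || is.null(abundance_data))) {
    stop("either sim or both data tables must be supplied")
  }
  structure(list(sim = sim, occupancy_data = occupancy_data,
                 abundance_data = abundance_data, mcmc = mcmc,
                 periods = periods, gl = gl, detection = detection,
                 species = species, out_dir = out_dir,
                 distance_filter_m = distance_filter_m,
                 rhat_threshold = rhat_threshold, force = force,
                 seed = as.integer(seed), verbose = verbose),
            class = "run_config")
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                               sprintf(fmt, ...)))
}

#' Run the full assessment pipeline
#'
#' Simulates (or loads) survey data, fits the occupancy model to the
#' detection histories and the count model to the seasonal maximum counts,
#' checks convergence of the key parameters, propagates the posterior draws
#' into between-period declines, classifies both data types under criterion
#' A2, and compares the resulting categories. Identical configurations
#' (including seed) reproduce identical outputs.
#'
#' @param config A [run_config()].
#' @return A list of class `trendrisk_run` with the fitted models, yearly
#'   indices, decline summaries, proportional changes, the two assessment
#'   reports and their comparison.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  v <- config$verbose
  if (!is.null(config$sim)) {
    stage_log(v, "simulating coupled dataset (%d sites)",
              config$sim$n_sites)
    sim <- simulate_coupled_dataset(config$sim)
    occ_data <- sim$occupancy
    ab_data <- sim$abundance
  } else {
    get_tab <- function(x) if (is.character(x)) read_survey_csv(x) else x
    occ_data <- get_tab(config$occupancy_data)
    ab_data <- get_tab(config$abundance_data)
    sim <- NULL
  }
  period_years <- unlist(lapply(config$periods, `[[`, "years"))
  data_years <- sort(unique(c(occ_data$year, ab_data$year)))
  if (!all(period_years %in% min(data_years):max(data_years))) {
    stop("assessment periods extend beyond the data years")
  }

  counts <- aggregate_max_count(ab_data)
  if (!is.null(config$distance_filter_m)) {
    occupied <- unique(counts$site_id[counts$count > 0])
    keep <- filter_sites_by_distance(counts, occupied,
                                     config$distance_filter_m)
    stage_log(v, "distance filter keeps %d/%d sites", length(keep),
              length(unique(counts$site_id)))
    counts <- counts[counts$site_id %in% keep, ]
  }

  occ_mcmc <- config$mcmc
  occ_mcmc$seed <- config$seed
  ab_mcmc <- config$mcmc
  ab_mcmc$seed <- config$seed + 1L
  stage_log(v, "fitting occupancy model")
  fit_occ <- fit_occupancy(occ_data, occ_mcmc)
  stage_log(v, "fitting %s count model",
            if (config$detection) "binomial mixture" else "census NB")
  fit_ab <- if (config$detection) {
    fit_nmixture(counts, ab_mcmc, detection = TRUE)
  } else {
    fit_abundance_glmm(counts, ab_mcmc)
  }

  gate <- c(occ = unname(fit_occ$rhat["beta_trend"]),
            occ_alpha = unname(fit_occ$rhat["alpha"]),
            ab = unname(fit_ab$rhat["beta_trend"]),
            ab_alpha = unname(fit_ab$rhat["alpha"]))
  if (any(gate > config$rhat_threshold, na.rm = TRUE) && !config$force) {
    stop("convergence gate failed (Rhat > ", config$rhat_threshold,
         " for alpha or beta_trend); rerun with more iterations or force")
  }

  assess_years <- sort(unique(period_years))
  declines_for <- function(fit, index_fun) {
    idx_T <- index_fun(fit, years = assess_years,
                       include_year_effects = TRUE, extrapolate = TRUE,
                       seed = config$seed + 2L)
    idx_trend <- index_fun(fit, years = range(fit$years),
                           include_year_effects = FALSE)
    pairs <- list()
    for (k in seq_len(length(config$periods) - 1)) {
      pa <- config$periods[[k]]
      pb <- config$periods[[k + 1]]
      pairs[[paste(pa$label, pb$label, sep = "-")]] <-
        decline_between_periods(idx_T, pa, pb, gl = config$gl)
    }
    list(declines = pairs, change = proportional_change(idx_trend),
         index = idx_T)
  }
  stage_log(v, "deriving decline statistics")
  occ_der <- declines_for(fit_occ, predict_yearly_occupied)
  ab_der <- declines_for(fit_ab, predict_yearly_abundance)

  report_occ <- assessment_report(config$species, "occupancy",
                                  occ_der$declines)
  report_ab <- assessment_report(config$species, "abundance",
                                 ab_der$declines)
  comparison <- compare_data_types(report_occ, report_ab)

  out <- structure(
    list(config = config, fit_occupancy = fit_occ, fit_abundance = fit_ab,
         occ = occ_der, abund = ab_der,
         report_occupancy = report_occ, report_abundance = report_ab,
         comparison = comparison, truth = sim$truth),
    class = "trendrisk_run")
  if (!is.null(config$out_dir)) write_run_artifacts(out, config$out_dir)
  out
}

#' @export
print.trendrisk_run <- function(x, ...) {
  cat("Occupancy vs abundance assessment\n\n")
  print(as.data.frame(x$comparison), row.names = FALSE)
  invisible(x)
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_draws_csv(run$fit_occupancy, file.path(out_dir, "draws_occupancy.csv"))
  write_draws_csv(run$fit_abundance, file.path(out_dir, "draws_abundance.csv"))
  both <- rbind(as.data.frame(run$report_occupancy),
                as.data.frame(run$report_abundance))
  utils::write.csv(both, file.path(out_dir, "assessment_report.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(run$comparison),
                   file.path(out_dir, "comparison.csv"), row.names = FALSE)
  cfg <- run$config
  manifest <- list(
    package_version = as.character(utils::packageVersion("trendrisk")),
    seed = cfg$seed, species = cfg$species, gl = cfg$gl,
    detection = cfg$detection,
    mcmc = unclass(cfg$mcmc),
    periods = lapply(cfg$periods, function(p) {
      list(label = p$label, years = p$years)
    }),
    sim = if (!is.null(cfg$sim)) {
      lapply(unclass(cfg$sim), function(v) {
        if (is.numeric(v) || is.character(v) || is.logical(v)) v else NULL
      })
    })
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Split-chain potential scale reduction (Rhat)
#'
#' Classic split-Rhat: each chain is split in half, and the statistic
#' compares between- and within-half variances; values near 1 indicate the
#' chains sample the same distribution. Values above about 1.1 indicate
#' non-convergence.
#'
#' @param x A `trend_fit`, or a matrix of draws with one column per chain.
#' @param param Parameter name, required when `x` is a fit.
#' @return Rhat (numeric scalar).
#' @export
compute_rhat <- function(x, param = NULL) {
  if (inherits(x, "trend_fit")) {
    stopifnot(!is.null(param))
    v <- x$draws[[param]]
    if (is.null(v)) stop("unknown parameter: ", param)
    x <- do.call(cbind, split(v, x$chain))
  }
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("Rhat needs at least 2 chains")
  if (nrow(x) < 4) stop("chains too short to split")
  split_rhat(x)
}
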