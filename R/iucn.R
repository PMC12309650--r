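# IUCN Red List criterion A2 classification of decline rates and the
# occupancy-vs-abundance comparison report.

iucn_levels <- c("LC", "NT", "VU", "EN", "CR")

#' Classify a population reduction under criterion A2
#'
#' Maps a decline over the assessment window (proportion, positive =
#' decline) to the ordered categories used here: LC below 20%, NT at >= 20%,
#' VU at >= 30%, EN at >= 50%, CR at >= 80% (thresholds inclusive upward;
#' the 20% NT convention follows common practice for flagging
#' near-threatened reductions). Increases and zero declines are LC.
#'
#' @param decline Numeric vector of declines over the assessment window;
#'   values > 1 are rejected.
#' @return Ordered factor with levels `LC < NT < VU < EN < CR`.
#' @export
classify_decline <- function(decline) {
  if (any(decline > 1)) stop("a decline cannot exceed 1 (complete loss)")
  idx <- findInterval(decline, c(0.20, 0.30, 0.50, 0.80)) + 1L
  idx[decline < 0.20] <- 1L
  factor(iucn_levels[idx], levels = iucn_levels, ordered = TRUE)
}

#' Threat category from a posterior decline summary
#'
#' In `"median"` mode the posterior-median decline rate is classified (the
#' derived-parameter convention: the median of per-draw rates, not the rate
#' of median abundances). In `"draws"` mode every posterior draw is
#' classified and the posterior probability of each category is returned,
#' quantifying assessment uncertainty.
#'
#' @param decline A `decline_summary` from [decline_between_periods()].
#' @param on `"median"` or `"draws"`.
#' @return `"median"`: a single ordered factor level. `"draws"`: named
#'   numeric vector of per-category posterior probabilities (summing to 1),
#'   with the modal category as attribute `modal`.
#' @export
assess <- function(decline, on = c("median", "draws")) {
  stopifnot(inherits(decline, "decline_summary"))
  on <- match.arg(on)
  D_draws <- -decline$rate              # positive = decline
  if (on == "median") {
    return(classify_decline(stats::median(D_draws)))
  }
  cats <- classify_decline(D_draws)
  prob <- table(cats) / length(cats)
  out <- stats::setNames(as.numeric(prob), names(prob))
  attr(out, "modal") <- names(out)[which.max(out)]
  out
}

#' Assemble an assessment report
#'
#' One row per species x data type x period pair, carrying the category,
#' the decline probability and the decline-rate summary.
#'
#' @param species Species label.
#' @param data_type `"occupancy"` or `"abundance"`.
#' @param declines Named list of `decline_summary` objects; names label the
#'   period pairs (e.g. `"tau1-tau2"`).
#' @return Data frame of class `assessment_report`.
#' @export
assessment_report <- function(species, data_type, declines) {
  stopifnot(length(declines) >= 1, !is.null(names(declines)))
  rows <- lapply(names(declines), function(nm) {
    d <- declines[[nm]]
    data.frame(species = species, data_type = data_type, period_pair = nm,
               category = as.character(assess(d, "median")),
               Dp = d$Dp, rate_median = d$rate_median,
               rate_lo = d$rate_lower, rate_hi = d$rate_upper,
               L = d$L, GL = d$GL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("assessment_report", "data.frame")
  out
}

#' Compare occupancy-based and abundance-based threat categories
#'
#' Joins two assessment reports on species and period pair and computes the
#' signed category-rank difference (abundance rank minus occupancy rank;
#' positive means abundance data place the species in a higher threat
#' category) and its absolute value.
#'
#' @param report_occ,report_abund `assessment_report` objects for the same
#'   species/period pairs.
#' @return Data frame with one row per species x period pair: both
#'   categories, both decline probabilities, CI widths, the signed rank
#'   difference and the category distance.
#' @export
compare_data_types <- function(report_occ, report_abund) {
  key <- c("species", "period_pair")
  merged <- merge(as.data.frame(report_occ), as.data.frame(report_abund),
                  by = key, suffixes = c("_occ", "_abund"))
  if (nrow(merged) == 0) stop("no matching species/period pairs")
  rank_occ <- match(merged$category_occ, iucn_levels)
  rank_abund <- match(merged$category_abund, iucn_levels)
  out <- data.frame(
    species = merged$species, period_pair = merged$period_pair,
    category_occ = merged$category_occ,
    category_abund = merged$category_abund,
    Dp_occ = merged$Dp_occ, Dp_abund = merged$Dp_abund,
    rate_median_occ = merged$rate_median_occ,
    rate_median_abund = merged$rate_median_abund,
    ci_width_occ = merged$rate_hi_occ - merged$rate_lo_occ,
    ci_width_abund = merged$rate_hi_abund - merged$rate_lo_abund,
    rank_difference = rank_abund - rank_occ,
    category_distance = abs(rank_abund - rank_occ))
  class(out) <- c("assessment_comparison", "data.frame")
  out
}
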