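# Derived decline statistics: everything is computed per posterior draw
# first and summarized last, so credible intervals on the final quantities
# carry full parameter uncertainty.

#' Define an assessment period
#'
#' @param label Period label (e.g. `"tau1"`).
#' @param years Calendar years belonging to the period.
#' @return An object of class `period`.
#' @export
period <- function(label, years) {
  stopifnot("period needs at least one year" = length(years) >= 1)
  structure(list(label = label, years = as.integer(years)),
            class = "period")
}

#' @export
print.period <- function(x, ...) {
  cat(sprintf("period %s: %d-%d (%d years)\n", x$label, min(x$years),
              max(x$years), length(x$years)))
  invisible(x)
}

#' Default three-period split of the study window
#'
#' Periods 1996--2003, 2004--2011 and 2017--2022 (no surveys in 2012--2016),
#' each containing a similar number of sampling years.
#'
#' @return Named list of three [period()] objects.
#' @export
default_periods <- function() {
  list(tau1 = period("tau1", 1996:2003),
       tau2 = period("tau2", 2004:2011),
       tau3 = period("tau3", 2017:2022))
}

#' Elapsed time between two periods
#'
#' Defined as the difference of the periods' mean calendar years — the
#' definition under which the default periods give 8 years between the
#' first and second periods and 12 years between the second and third.
#'
#' @param period_a,period_b [period()] objects, `period_a` earlier.
#' @return Elapsed years (numeric scalar).
#' @export
elapsed_years <- function(period_a, period_b) {
  stopifnot(inherits(period_a, "period"), inherits(period_b, "period"))
  mean(period_b$years) - mean(period_a$years)
}

#' Per-draw mean of a yearly index over a period
#'
#' @param index A `yearly_index`.
#' @param period A [period()]; its years must all be present in the index.
#' @return Numeric vector: one mean per posterior draw.
#' @export
period_mean <- function(index, period) {
  stopifnot(inherits(index, "yearly_index"), inherits(period, "period"))
  idx <- match(period$years, attr(index, "years"))
  if (anyNA(idx)) {
    stop("period years ", paste(period$years[is.na(idx)], collapse = ", "),
         " are not in the index")
  }
  rowMeans(unclass(index)[, idx, drop = FALSE])
}

#' Proportional change over the study period
#'
#' Per draw, the ratio of the yearly index in the last year to the first
#' year. The index should be built with `include_year_effects = FALSE` so
#' that the ratio reflects the estimated trend, not random yearly
#' fluctuations; a warning is issued otherwise.
#'
#' @param index A `yearly_index`.
#' @return List with per-draw `ratio`, the median and equal-tailed 95%
#'   interval, and `excludes_one` (does the interval exclude 1, the no-change
#'   value?). Draws with a zero starting index are excluded and counted in
#'   `n_degenerate`.
#' @export
proportional_change <- function(index) {
  stopifnot(inherits(index, "yearly_index"))
  if (isTRUE(attr(index, "include_year_effects"))) {
    warning("proportional change is defined on the trend-only index ",
            "(include_year_effects = FALSE)", call. = FALSE)
  }
  m <- unclass(index)
  first <- m[, 1]
  last <- m[, ncol(m)]
  bad <- first == 0
  if (any(bad)) {
    message(sum(bad), " draw(s) with zero index in the first year excluded")
  }
  ratio <- last[!bad] / first[!bad]
  ci <- stats::quantile(ratio, c(0.025, 0.975))
  list(ratio = ratio, median = stats::median(ratio),
       lower = ci[[1]], upper = ci[[2]],
       excludes_one = ci[[1]] > 1 || ci[[2]] < 1,
       n_degenerate = sum(bad))
}

#' Between-period decline with full uncertainty propagation
#'
#' For each posterior draw, the signed change between two periods is
#' `C = mean_b / mean_a - 1` (negative = decline) and the decline is
#' `D = -C`. `D` is converted per draw to an annual decline
#' `Da = 1 - (1 - D)^(1/L)` over the `L` years separating the period
#' midpoints, and compounded over the assessment window as
#' `Dr = 1 - (1 - Da)^GL`, with `GL` the longer of 10 years and three times
#' the species' generation length. The reported signed rate is `-Dr`
#' (negative = decline), matching the convention that credible intervals
#' may span positive values when an increase is plausible.
#'
#' @param index A `yearly_index` built with `include_year_effects = TRUE`
#'   (period means average over realized yearly fluctuations; see the
#'   methods vignette for the alternative convention).
#' @param period_a,period_b [period()] objects, `period_a` strictly earlier.
#' @param gl Assessment window in years (>= 10).
#' @return An object of class `decline_summary`: per-draw `C` and signed
#'   rate draws, `Dp` (decline probability: fraction of draws with `C < 0`;
#'   exact zeros count as non-decline), median and equal-tailed 95% CI of
#'   the signed rate, `L`, `GL`, and the count of draws flagged as total
#'   extirpation (`D >= 1`, mapped to rate 1).
#' @export
decline_between_periods <- function(index, period_a, period_b, gl = 10) {
  stopifnot(inherits(index, "yearly_index"))
  if (gl < 10) stop("the assessment window GL must be at least 10 years")
  L <- elapsed_years(period_a, period_b)
  if (L <= 0) stop("period_a must precede period_b")
  mean_a <- period_mean(index, period_a)
  mean_b <- period_mean(index, period_b)
  bad <- mean_a == 0
  if (any(bad)) {
    message(sum(bad), " draw(s) with zero mean in the earlier period excluded")
  }
  C <- mean_b[!bad] / mean_a[!bad] - 1
  D <- -C
  extirpated <- D >= 1
  Da <- annual_decline(pmin(D, 1), L)
  Dr <- decline_rate(Da, gl)
  rate <- -Dr
  ci <- stats::quantile(rate, c(0.025, 0.975))
  structure(
    list(C = C, rate = rate, Dp = decline_probability_raw(C),
         rate_median = stats::median(rate),
         rate_lower = ci[[1]], rate_upper = ci[[2]],
         L = L, GL = gl, n_extirpated = sum(extirpated),
         n_degenerate = sum(bad),
         period_a = period_a, period_b = period_b,
         kind = attr(index, "kind")),
    class = "decline_summary")
}

#' @export
print.decline_summary <- function(x, ...) {
  cat(sprintf("Decline %s -> %s (%s): L = %g yr, GL = %g yr\n",
              x$period_a$label, x$period_b$label, x$kind, x$L, x$GL))
  cat(sprintf("  decline probability Dp = %.3f\n", x$Dp))
  cat(sprintf("  signed decline rate: %.3f [%.3f, %.3f]\n",
              x$rate_median, x$rate_lower, x$rate_upper))
  invisible(x)
}

decline_probability_raw <- function(C) mean(C < 0)

#' Posterior probability of decline
#'
#' The fraction of posterior draws in which the between-period change is
#' negative; draws exactly at zero count as non-decline.
#'
#' @param x A `decline_summary` or a numeric vector of per-draw signed
#'   changes `C`.
#' @return `Dp` in `[0, 1]`.
#' @export
decline_probability <- function(x) {
  if (inherits(x, "decline_summary")) return(decline_probability_raw(x$C))
  decline_probability_raw(x)
}

#' Annualize a total decline
#'
#' `Da = 1 - (1 - D)^(1/L)`: the constant yearly decline that compounds to
#' the total decline `D` over `L` years. Negative `D` (an increase) is
#' allowed; `D >= 1` (total extirpation) is mapped to `Da = 1` with a
#' warning.
#'
#' @param D Total decline (proportion, < 1 for surviving populations).
#' @param L Elapsed years (> 0).
#' @return Annual decline(s).
#' @export
annual_decline <- function(D, L) {
  stopifnot("L must be > 0" = L > 0)
  if (any(D > 1)) stop("a decline cannot exceed 1 (complete loss)")
  out <- 1 - (1 - D)^(1 / L)
  if (any(D == 1)) {
    warning("total extirpation (D = 1): annual decline set to 1",
            call. = FALSE)
    out[D == 1] <- 1
  }
  out
}

#' Rescale an annual decline to the IUCN assessment window
#'
#' `Dr = 1 - (1 - Da)^GL`: the decline accumulated over `GL` years at
#' constant annual decline `Da`. `decline_rate(annual_decline(D, L), L)`
#' recovers `D` exactly. For threat assessment `GL` is the longer of 10
#' years and three times the generation length; the function itself accepts
#' any positive window so the compounding algebra stays exact.
#'
#' @param Da Annual decline(s) (<= 1).
#' @param GL Assessment window in years (> 0).
#' @return Decline rate(s) over the window.
#' @export
decline_rate <- function(Da, GL) {
  stopifnot("GL must be > 0" = GL > 0, "Da must be <= 1" = all(Da <= 1))
  1 - (1 - Da)^GL
}

#' Display transform for decline probabilities
#'
#' `-log(1 - Dp)` spreads the crowded high-probability end of the `Dp`
#' scale. `Dp = 1` (every draw declining) is capped at the value
#' corresponding to `1 - 1/n_draws`, the finest probability the posterior
#' sample can resolve.
#'
#' @param Dp Decline probabilities in `[0, 1]`.
#' @param n_draws Posterior sample size used for the cap at `Dp = 1`.
#' @return Transformed values.
#' @export
display_transform_dp <- function(Dp, n_draws = 3000) {
  stopifnot(all(Dp >= 0 & Dp <= 1))
  capped <- pmin(Dp, 1 - 1 / n_draws)
  -log(1 - capped)
}
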