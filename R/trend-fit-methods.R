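# S3 methods shared by the three fitted-model classes.

#' @export
print.trend_fit <- function(x, ...) {
  label <- switch(x$model,
                  occupancy = "Occupancy trend model (imperfect detection)",
                  nb_glmm = "Negative-binomial abundance trend model",
                  nmixture = "Binomial mixture abundance trend model")
  cat(label, "\n")
  cat(sprintf("  %d sites, %d years (%g-%g), year %g centered to 0\n",
              length(x$sites), length(x$years), min(x$years), max(x$years),
              x$center_year))
  cat(sprintf("  %d posterior draws (%d chains x %d)\n",
              x$n_draws, x$mcmc$n_chains, x$mcmc$n_keep))
  bt <- stats::quantile(x$draws$beta_trend, c(0.025, 0.5, 0.975))
  cat(sprintf("  beta_trend: %.4f [%.4f, %.4f] per year\n",
              bt[2], bt[1], bt[3]))
  if (!all(is.na(x$rhat))) {
    cat(sprintf("  max Rhat (key parameters): %.3f\n",
                max(x$rhat, na.rm = TRUE)))
  }
  invisible(x)
}

#' Posterior summaries of a fitted trend model
#'
#' @param object A `trend_fit`.
#' @param prob Credible-interval mass (equal-tailed).
#' @param ... Unused.
#' @return Data frame with posterior median, equal-tailed interval and Rhat
#'   (where computed) per scalar parameter.
#' @export
summary.trend_fit <- function(object, prob = 0.95, ...) {
  a <- (1 - prob) / 2
  scalars <- Filter(function(v) is.numeric(v) && !is.matrix(v), object$draws)
  scalars$loglik <- NULL
  out <- do.call(rbind, lapply(names(scalars), function(nm) {
    q <- stats::quantile(scalars[[nm]], c(a, 0.5, 1 - a))
    data.frame(parameter = nm, median = q[2], lower = q[1], upper = q[3],
               rhat = if (nm %in% names(object$rhat)) {
                 object$rhat[[nm]]
               } else {
                 NA_real_
               })
  }))
  rownames(out) <- NULL
  out
}

#' @export
coef.trend_fit <- function(object, ...) {
  scalars <- Filter(function(v) is.numeric(v) && !is.matrix(v), object$draws)
  scalars$loglik <- NULL
  vapply(scalars, stats::median, numeric(1))
}

#' Posterior yearly index from a fitted trend model
#'
#' Dispatches to [predict_yearly_occupied()] or
#' [predict_yearly_abundance()] according to the model class.
#'
#' @param object A `trend_fit`.
#' @param years Calendar years to evaluate.
#' @param include_year_effects Include the year random effects?
#' @param extrapolate Allow years outside the fitted range.
#' @param seed Optional seed for prior draws in unfitted years.
#' @param ... Unused.
#' @return A `yearly_index`.
#' @export
predict.trend_fit <- function(object, years = object$years,
                              include_year_effects = FALSE,
                              extrapolate = FALSE, seed = NULL, ...) {
  if (object$model == "occupancy") {
    predict_yearly_occupied(object, years, include_year_effects,
                            extrapolate, seed)
  } else {
    predict_yearly_abundance(object, years, include_year_effects,
                             extrapolate, seed)
  }
}

#' Write posterior draws to a long-format CSV
#'
#' One row per draw x parameter, with chain and iteration columns, so draws
#' survive a round trip through plain text.
#'
#' @param fit A `trend_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(fit, path) {
  dr <- fit$draws
  flat <- lapply(names(dr), function(nm) {
    v <- dr[[nm]]
    if (is.matrix(v)) {
      do.call(rbind, lapply(seq_len(ncol(v)), function(j) {
        data.frame(chain = fit$chain,
                   iteration = stats::ave(fit$chain, fit$chain,
                                          FUN = seq_along),
                   parameter = paste0(nm, "[", colnames(v)[j], "]"),
                   value = v[, j])
      }))
    } else {
      data.frame(chain = fit$chain,
                 iteration = stats::ave(fit$chain, fit$chain,
                                        FUN = seq_along),
                 parameter = nm, value = v)
    }
  })
  utils::write.csv(do.call(rbind, flat), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
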