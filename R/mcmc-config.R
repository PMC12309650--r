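#' MCMC settings for the trend models
#'
#' Defaults follow the long-run convention used for the production analyses:
#' 3 chains of 400,000 iterations, the first 300,000 discarded as burn-in,
#' and the remainder thinned to 1000 retained draws per chain. Tests and
#' examples use much shorter runs, e.g.
#' `mcmc_config(n_iterations = 4000, n_burnin = 1000)`.
#'
#' @param n_chains Number of chains (>= 1; >= 2 needed for Rhat).
#' @param n_iterations Total iterations per chain.
#' @param n_burnin Iterations discarded as burn-in (also the adaptation
#'   window for the proposal scales).
#' @param thin_to Target number of retained draws per chain; the thinning
#'   interval is `floor((n_iterations - n_burnin) / thin_to)`.
#' @param seed Integer seed controlling every stochastic element of the fit.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iterations = 400000L,
                        n_burnin = 300000L, thin_to = 1000L, seed = 1L) {
  stopifnot(
    "n_chains must be >= 1" = n_chains >= 1,
    "n_burnin must be < n_iterations" = n_burnin < n_iterations,
    "thin_to must be >= 1" = thin_to >= 1,
    "seed must be a single integer" = is.numeric(seed) && length(seed) == 1
  )
  post <- n_iterations - n_burnin
  thin <- max(1L, as.integer(floor(post / thin_to)))
  keep <- min(as.integer(thin_to), as.integer(floor(post / thin)))
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin),
                 thin_to = as.integer(thin_to),
                 thin = thin, n_keep = keep, seed = as.integer(seed)),
            class = "mcmc_config")
}

#' @export
print.mcmc_config <- function(x, ...) {
  cat(sprintf(
    "MCMC: %d chains x %d iterations (%d burn-in), thin %d -> %d draws/chain, seed %d\n",
    x$n_chains, x$n_iterations, x$n_burnin, x$thin, x$n_keep, x$seed))
  invisible(x)
}
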