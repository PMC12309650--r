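# Shared internals for the model-fitting front ends.

# Index structures handed to the compiled samplers. Rows must already be
# ordered so that site-years are contiguous within sites.
build_groupings <- function(sy_site, sy_year, n_sites, n_years) {
  n_sy <- length(sy_site)
  site_sy_ptr <- c(0L, cumsum(tabulate(sy_site, n_sites)))
  year_ord <- order(sy_year)
  year_sy_idx <- as.integer(year_ord - 1L)
  year_sy_ptr <- c(0L, cumsum(tabulate(sy_year, n_years)))
  list(site_sy_ptr = as.integer(site_sy_ptr),
       year_sy_idx = year_sy_idx,
       year_sy_ptr = as.integer(year_sy_ptr),
       n_sy = n_sy)
}

resolve_center_year <- function(center_year, years) {
  if (is.null(center_year)) center_year <- stats::median(years)
  center_year
}

# Split-chain potential scale reduction on a draws matrix laid out as
# (iterations x chains); used both by compute_rhat() and at fit time.
split_rhat <- function(mat) {
  n <- nrow(mat)
  if (n %% 2 == 1) mat <- mat[-1, , drop = FALSE]
  half <- nrow(mat) / 2
  halves <- cbind(mat[seq_len(half), , drop = FALSE],
                  mat[half + seq_len(half), , drop = FALSE])
  m <- ncol(halves)
  n2 <- nrow(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- n2 * stats::var(means)
  if (!is.finite(W) || W == 0) {
    # all-constant chains: identical chains are "converged"
    return(if (stats::var(as.vector(halves)) == 0) 1 else Inf)
  }
  var_plus <- (n2 - 1) / n2 * W + B / n2
  sqrt(var_plus / W)
}

fit_rhat <- function(draws, chain, params) {
  if (length(unique(chain)) < 2) {
    return(stats::setNames(rep(NA_real_, length(params)), params))
  }
  out <- vapply(params, function(p) {
    v <- draws[[p]]
    split_rhat(do.call(cbind, split(v, chain)))
  }, numeric(1))
  out
}

# Jitter one set of central initial values into per-chain dispersed inits.
jitter_init <- function(init, scales) {
  for (nm in names(scales)) {
    init[[nm]] <- init[[nm]] + stats::rnorm(length(init[[nm]]), 0, scales[[nm]])
  }
  init
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

new_trend_fit <- function(subclass, model, chains, mcmc, sites, years,
                          center_year, extra = list()) {
  n_keep <- mcmc$n_keep
  bind <- function(nm) {
    parts <- lapply(chains, `[[`, nm)
    if (is.matrix(parts[[1]])) do.call(rbind, parts) else unlist(parts)
  }
  draws <- stats::setNames(lapply(names(chains[[1]]), bind), names(chains[[1]]))
  if (!is.null(draws$T)) colnames(draws$T) <- as.character(years)
  if (!is.null(draws$S)) colnames(draws$S) <- sites
  if (!is.null(draws$Sp)) colnames(draws$Sp) <- sites
  chain <- rep(seq_along(chains), each = n_keep)
  obj <- c(list(model = model, draws = draws, chain = chain,
                n_draws = length(chain), sites = sites, years = years,
                center_year = center_year, mcmc = mcmc),
           extra)
  structure(obj, class = c(subclass, "trend_fit"))
}

warn_if_unconverged <- function(fit, threshold = 1.1) {
  key <- intersect(c("alpha", "beta_trend"), names(fit$rhat))
  bad <- key[!is.na(fit$rhat[key]) & fit$rhat[key] > threshold]
  if (length(bad)) {
    warning("possible non-convergence: Rhat > ", threshold, " for ",
            paste(bad, collapse = ", "), call. = FALSE)
  }
  fit
}
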