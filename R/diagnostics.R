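# Posterior summaries, convergence diagnostics, and model comparison.

#' Posterior summary table
#'
#' Pools all chains and reports, per parameter, the mean, standard
#' deviation, and 2.5/25/50/75/97.5 percentiles of the retained draws
#' (linear-interpolation quantiles, R type 7, so output is reproducible).
#' For parameters sampled on the unconstrained scale (learning rate,
#' starting point), additional rows named `<parameter>_trans` report the
#' inverse-logit transformed draws.
#'
#' @param store A `posterior_store`.
#' @param transformed Add the `_trans` rows.
#' @return A data frame with columns `mean, std, 2.5q, 25q, 50q, 75q, 97.5q`
#'   and one row per parameter (rownames).
#' @export
posterior_summary <- function(store, transformed = TRUE) {
  m <- pooled_draws(store)
  m <- m[, setdiff(colnames(m), "deviance"), drop = FALSE]
  if (transformed && length(store$transformed) > 0) {
    tm <- invlogit(m[, intersect(store$transformed, colnames(m)), drop = FALSE])
    colnames(tm) <- paste0(colnames(tm), "_trans")
    m <- cbind(m, tm)
  }
  qs <- t(apply(m, 2, stats::quantile,
                probs = c(0.025, 0.25, 0.5, 0.75, 0.975), type = 7))
  out <- data.frame(mean = colMeans(m), std = apply(m, 2, stats::sd),
                    qs, check.names = FALSE)
  colnames(out) <- c("mean", "std", "2.5q", "25q", "50q", "75q", "97.5q")
  out
}

#' Write a posterior summary table to CSV
#'
#' Header is exactly `mean,std,2.5q,25q,50q,75q,97.5q`; parameter names are
#' the row names.
#'
#' @param summary A data frame from [posterior_summary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = ",", quote = FALSE,
                     row.names = TRUE, col.names = TRUE)
  invisible(path)
}

#' Gelman-Rubin convergence statistic
#'
#' The classic potential-scale-reduction factor: with `m` chains of length
#' `n`, within-chain variance `W` and between-chain variance `B`,
#' `R = sqrt(((n-1)/n * W + B/n) / W)`. Values near 1 indicate that the
#' chains sample the same distribution; the common convergence heuristic is
#' `R < 1.1` for every parameter, surfaced here as the `"converged"`
#' attribute.
#'
#' @param stores A `posterior_store` with at least two chains, or a list of
#'   stores over identical models (their chains are combined).
#' @return Named vector of statistics per parameter, with attribute
#'   `converged` (all values below 1.1).
#' @export
gelman_rubin <- function(stores) {
  chains <- if (inherits(stores, "posterior_store")) stores$draws
            else do.call(c, lapply(stores, function(s) s$draws))
  if (length(chains) < 2)
    abort_precondition("gelman_rubin needs at least 2 chains")
  lens <- vapply(chains, nrow, integer(1))
  if (length(unique(lens)) != 1)
    abort_precondition("chains must have equal retained lengths")
  pars <- setdiff(colnames(chains[[1]]), "deviance")
  n <- lens[1]
  r <- vapply(pars, function(p) {
    x <- vapply(chains, function(m) m[, p], numeric(n))
    W <- mean(apply(x, 2, stats::var))
    B_over_n <- stats::var(colMeans(x))
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }, numeric(1))
  attr(r, "converged") <- all(r < 1.1)
  r
}

#' Sample autocorrelation of one parameter's chain
#'
#' @param draws Numeric vector (one chain of one parameter).
#' @param max_lag Largest lag; must be smaller than the chain length.
#' @return Autocorrelations at lags `0..max_lag`.
#' @export
chain_autocorrelation <- function(draws, max_lag = 50) {
  if (length(draws) <= max_lag)
    abort_precondition("chain length must exceed max_lag")
  as.numeric(stats::acf(draws, lag.max = max_lag, plot = FALSE,
                        demean = TRUE)$acf)
}

# Effective sample size from the initial-positive-sequence autocorrelations.
effective_n <- function(draws) {
  n <- length(draws)
  rho <- chain_autocorrelation(draws, max_lag = min(n - 1, 200))[-1]
  pos <- which(rho <= 0)
  if (length(pos) > 0) rho <- rho[seq_len(pos[1] - 1)]
  max(1, n / (1 + 2 * sum(rho)))
}

#' Deviance information criterion
#'
#' `DIC = mean deviance + pD` with `pD = mean deviance - deviance at the
#' posterior mean`. Posterior means of transformed parameters are taken on
#' the unconstrained scale (the scale the sampler works on).
#'
#' @param store A `posterior_store` that retains a `deviance` column.
#' @param model The `rlddm_model` the store was sampled from (used to
#'   evaluate the deviance at the posterior mean).
#' @return List with elements `dic`, `pd`, and `mean_deviance`.
#' @export
dic <- function(store, model) {
  m <- pooled_draws(store)
  if (!"deviance" %in% colnames(m))
    abort_precondition("store lacks a deviance trace")
  dbar <- mean(m[, "deviance"])
  theta_bar <- colMeans(m[, model$state_names, drop = FALSE])
  dhat <- -2 * total_loglik(model, theta_bar)
  list(dic = dbar + (dbar - dhat), pd = dbar - dhat, mean_deviance = dbar)
}

# Shortest interval containing `prob` of the sample (highest-density
# interval under unimodality).
hdi <- function(x, prob = 0.9) {
  x <- sort(x)
  n <- length(x)
  k <- max(1, ceiling(prob * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}
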