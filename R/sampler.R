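# MCMC over the model graph: univariate slice sampling (stepping-out and
# shrinkage, Neal 2003) applied to each free node in turn. Transformed
# parameters are sampled on the unconstrained scale. Deterministic given the
# seed.

# One slice-sampling update. f is the conditional log-density; fx0 = f(x0).
slice_update <- function(f, x0, fx0, w = 1, max_steps = 10,
                         lower = -Inf, upper = Inf) {
  log_y <- fx0 - stats::rexp(1)
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  # stepping out, with a randomized split of the step budget
  j <- floor(max_steps * stats::runif(1))
  k <- max_steps - 1 - j
  while (j > 0 && L > lower && f(L) > log_y) { L <- L - w; j <- j - 1 }
  while (k > 0 && R < upper && f(R) > log_y) { R <- R + w; k <- k - 1 }
  L <- max(L, lower)
  R <- min(R, upper)
  # shrinkage
  for (rep in 1:1000) {
    x1 <- stats::runif(1, L, R)
    fx1 <- f(x1)
    if (fx1 >= log_y) return(list(x = x1, fx = fx1))
    if (x1 < x0) L <- x1 else R <- x1
  }
  list(x = x0, fx = fx0)  # numerically stuck: keep the current value
}

# Build the node list: for every free parameter its conditional log-density
# (prior structure plus the likelihood terms that involve it) and support.
make_nodes <- function(model) {
  nodes <- list()
  add <- function(nd) nodes[[length(nodes) + 1]] <<- nd
  for (fam in model$families) {
    iix <- model$ix[[fam$name]]
    mu_i <- iix$mu; sd_i <- iix$sd; subj_i <- iix$subj
    kind <- fam$subj_dist
    mu_prior <- fam$mu_prior; sd_prior <- fam$sd_prior
    add(list(idx = mu_i, name = model$state_names[mu_i],
             lower = if (mu_prior$dist == "gamma") 0 else -Inf, upper = Inf,
             logpost = local({
               mu_prior <- mu_prior; sd_i <- sd_i; subj_i <- subj_i; kind <- kind
               function(val, state)
                 prior_logd(mu_prior, val) +
                   subj_logd(kind, state[subj_i], val, state[sd_i])
             })))
    add(list(idx = sd_i, name = model$state_names[sd_i],
             lower = 0, upper = Inf,
             logpost = local({
               sd_prior <- sd_prior; mu_i <- mu_i; subj_i <- subj_i; kind <- kind
               function(val, state)
                 prior_logd(sd_prior, val) +
                   subj_logd(kind, state[subj_i], state[mu_i], val)
             })))
    for (j in seq_along(model$subjects)) {
      add(list(idx = subj_i[j], name = model$state_names[subj_i[j]],
               lower = if (kind == "gamma") 0 else -Inf, upper = Inf,
               logpost = local({
                 self_i <- subj_i[j]; mu_i <- mu_i; sd_i <- sd_i
                 kind <- kind; j <- j
                 function(val, state) {
                   lp <- subj_logd(kind, val, state[mu_i], state[sd_i])
                   if (!is.finite(lp)) return(-Inf)
                   state[self_i] <- val
                   lp + subject_loglik(model, state, j)
                 }
               })))
    }
  }
  for (vp in model$var_params) {
    vi <- model$ix[[vp]]$mu
    vprior <- model$priors[[vp]]
    add(list(idx = vi, name = vp, lower = 0,
             upper = if (vp == "sz") 1 else Inf,
             logpost = local({
               vprior <- vprior; vi <- vi
               function(val, state) {
                 lp <- prior_logd(vprior, val)
                 if (!is.finite(lp)) return(-Inf)
                 state[vi] <- val
                 lp + total_loglik(model, state)
               }
             })))
  }
  nodes
}

# Draw an initial state from the prior structure (uses the current RNG
# stream). Regression slopes start near zero, their prior mean, so that the
# implied trial-level thresholds are feasible.
draw_initial_state <- function(model) {
  state <- numeric(length(model$state_names))
  names(state) <- model$state_names
  for (fam in model$families) {
    iix <- model$ix[[fam$name]]
    is_slope <- fam$kind == "coef" && fam$term != "Intercept"
    mu <- if (is_slope) stats::rnorm(1, 0, 0.05) else prior_sample(fam$mu_prior)
    sdv <- max(prior_sample(fam$sd_prior), 1e-3)
    if (is_slope) sdv <- min(sdv, 0.05)
    subj <- subj_sample(fam$subj_dist, length(model$subjects), mu, sdv)
    if (fam$param == "t" && !model$prior_only) {
      # non-decision time must lie below each subject's fastest response
      for (j in seq_along(model$subjects)) {
        cap <- 0.9 * model$sdata[[j]]$min_rt
        tries <- 0
        while ((subj[j] < 0 || subj[j] >= cap) && tries < 5) {
          subj[j] <- stats::rnorm(1, mu, sdv)
          tries <- tries + 1
        }
        if (subj[j] < 0 || subj[j] >= cap) subj[j] <- stats::runif(1, 0, cap)
      }
      mu <- min(mu, min(vapply(model$sdata, `[[`, numeric(1), "min_rt")) * 0.9)
      if (mu < 0) mu <- mean(subj)
    }
    state[iix$mu] <- mu
    state[iix$sd] <- sdv
    state[iix$subj] <- subj
  }
  for (vp in model$var_params) {
    v <- prior_sample(model$priors[[vp]])
    if (vp == "st" && !model$prior_only) {
      tmin <- min(state[model$ix[["t"]]$subj])
      v <- min(v, max(2 * tmin - 1e-6, 0))
    }
    state[model$ix[[vp]]$mu] <- v
  }
  state
}

#' Draw an initial parameter state
#'
#' Group nodes are drawn from their priors and subject nodes from their
#' group distributions, retrying (bounded) until the joint log-density is
#' finite. Non-decision times are shrunk below each subject's fastest
#' response, as required by the first-passage support.
#'
#' @param model An `rlddm_model`.
#' @param seed Optional integer seed.
#' @param max_retries Attempts before giving up.
#' @return Named numeric state vector (unconstrained scale for transformed
#'   parameters).
#' @export
initialize_state <- function(model, seed = NULL, max_retries = 25) {
  if (!is.null(seed)) set.seed(seed)
  nodes <- make_nodes(model)
  for (attempt in seq_len(max_retries)) {
    state <- draw_initial_state(model)
    ok <- TRUE
    for (nd in nodes) {
      if (!is.finite(nd$logpost(state[nd$idx], state))) { ok <- FALSE; break }
    }
    if (ok) return(state)
  }
  abort_config(sprintf(
    "failed to find a finite initial state in %d attempts (last non-finite node: %s)",
    max_retries, nd$name))
}

#' Sample the posterior by slice-sampling MCMC
#'
#' Runs univariate slice sampling (stepping-out and shrinkage; initial width
#' 1 on the sampling scale, at most 10 interval expansions) over every free
#' node of the model graph, for one or more independent chains. Transformed
#' parameters (learning rate, starting point) are sampled on the
#' unconstrained scale. The run is deterministic given `seed`. A model built
#' without data (prior-only) samples its prior.
#'
#' @param model An `rlddm_model` from [build_model()].
#' @param n_samples Total draws per chain.
#' @param burn Initial draws discarded as burn-in (`< n_samples`).
#' @param chains Number of independent chains.
#' @param seed Integer seed controlling initialization and sampling.
#' @param width Initial slice width.
#' @param max_steps Maximum stepping-out expansions.
#' @param progress Print a progress line per 100 iterations.
#' @return A `posterior_store`: retained draws (per chain, with a
#'   `deviance` column), parameter names, and the sampler configuration.
#' @examples
#' d <- simulate_rlddm_dataset(2, pst_schedule(10), seed = 1)
#' fit <- sample_posterior(build_model(d), n_samples = 50, burn = 10, seed = 1)
#' posterior_summary(fit)[c("a", "v", "alpha"), ]
#' @export
sample_posterior <- function(model, n_samples = 1500, burn = 500, chains = 1,
                             seed = 1, width = 1, max_steps = 10,
                             progress = FALSE) {
  if (!inherits(model, "rlddm_model")) abort_config("model must be an rlddm_model")
  if (burn >= n_samples) abort_config("burn must be smaller than n_samples")
  if (chains < 1) abort_config("chains must be >= 1")
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max, chains)
  nodes <- make_nodes(model)
  n_keep <- n_samples - burn
  draws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    state <- initialize_state(model)
    out <- matrix(NA_real_, n_keep, length(state) + 1L,
                  dimnames = list(NULL, c(model$state_names, "deviance")))
    for (it in seq_len(n_samples)) {
      for (nd in nodes) {
        x0 <- state[nd$idx]
        res <- slice_update(function(x) nd$logpost(x, state), x0,
                            nd$logpost(x0, state), w = width,
                            max_steps = max_steps,
                            lower = nd$lower, upper = nd$upper)
        state[nd$idx] <- res$x
      }
      if (it > burn) {
        out[it - burn, ] <- c(state, -2 * total_loglik(model, state))
      }
      if (progress && it %% 100 == 0)
        message(sprintf("chain %d: %d / %d", ch, it, n_samples))
    }
    draws[[ch]] <- out
  }
  structure(list(draws = draws, pars = model$state_names,
                 transformed = model$transformed,
                 config = list(n_samples = n_samples, burn = burn,
                               chains = chains, seed = seed, width = width,
                               max_steps = max_steps),
                 spec = model$spec, subjects = model$subjects),
            class = "posterior_store")
}

#' @export
print.posterior_store <- function(x, ...) {
  cat(sprintf("posterior_store: %d chain(s) x %d retained draws, %d parameters\n",
              length(x$draws), nrow(x$draws[[1]]), length(x$pars)))
  invisible(x)
}

# Pooled draw matrix across chains (parameters + deviance).
pooled_draws <- function(store) do.call(rbind, store$draws)

#' Serialize a posterior store to long-format CSV (+ YAML sidecar)
#'
#' Columns `chain, draw, parameter, value`; sampler configuration and
#' parameter metadata go to `<path>.meta.yaml`.
#'
#' @param store A `posterior_store`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(store, path) {
  rows <- do.call(rbind, lapply(seq_along(store$draws), function(ch) {
    m <- store$draws[[ch]]
    data.frame(chain = ch, draw = rep(seq_len(nrow(m)), ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  }))
  utils::write.table(rows, path, sep = ",", quote = FALSE, row.names = FALSE)
  meta <- list(config = store$config, pars = store$pars,
               transformed = as.list(store$transformed),
               subjects = store$subjects)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a posterior store written by [write_posterior()]
#' @param path CSV path (expects the `.meta.yaml` sidecar next to it).
#' @return A `posterior_store`.
#' @export
read_posterior <- function(path) {
  rows <- utils::read.table(path, header = TRUE, sep = ",",
                            stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  pars <- unique(rows$parameter)
  draws <- lapply(sort(unique(rows$chain)), function(ch) {
    sub <- rows[rows$chain == ch, ]
    m <- matrix(NA_real_, max(sub$draw), length(pars),
                dimnames = list(NULL, pars))
    for (p in pars) m[, p] <- sub$value[sub$parameter == p]
    m
  })
  structure(list(draws = draws, pars = setdiff(pars, "deviance"),
                 transformed = unlist(meta$transformed) %||% character(0),
                 config = meta$config, spec = NULL,
                 subjects = meta$subjects),
            class = "posterior_store")
}
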