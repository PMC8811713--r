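# The hierarchical prior structure.
#
# Group means and SDs are given informative priors taken from a meta-analysis
# of DDM fits (thresholds and non-decision times positive via Gamma priors);
# the learning-rate group mean has a wide normal prior on the unconstrained
# scale, centred at invlogit(0) = 0.5 after transformation. Subject-level
# learning rates and starting points live on the unconstrained scale and are
# mapped to (0, 1) by the inverse logit.

prior_normal <- function(mean, sd) {
  structure(list(dist = "normal", mean = mean, sd = sd,
                 ld = function(x) stats::dnorm(x, mean, sd, log = TRUE),
                 r = function(n) stats::rnorm(n, mean, sd),
                 analytic_mean = mean),
            class = "rlddm_prior")
}

# Gamma parameterized by mean and rate: shape = mean * rate.
prior_gamma_mean_rate <- function(mean, rate) {
  shape <- mean * rate
  structure(list(dist = "gamma", mean = mean, rate = rate, shape = shape,
                 ld = function(x) ifelse(x > 0,
                   stats::dgamma(x, shape = shape, rate = rate, log = TRUE), -Inf),
                 r = function(n) stats::rgamma(n, shape = shape, rate = rate),
                 analytic_mean = mean),
            class = "rlddm_prior")
}

# Half-normal parameterized by its scale (the SD of the underlying normal).
prior_halfnormal <- function(sigma) {
  structure(list(dist = "halfnormal", sigma = sigma,
                 ld = function(x) ifelse(x > 0,
                   stats::dnorm(x, 0, sigma, log = TRUE) + log(2), -Inf),
                 r = function(n) abs(stats::rnorm(n, 0, sigma)),
                 analytic_mean = sigma * sqrt(2 / pi)),
            class = "rlddm_prior")
}

prior_beta <- function(shape1, shape2) {
  structure(list(dist = "beta", shape1 = shape1, shape2 = shape2,
                 ld = function(x) stats::dbeta(x, shape1, shape2, log = TRUE),
                 r = function(n) stats::rbeta(n, shape1, shape2),
                 analytic_mean = shape1 / (shape1 + shape2)),
            class = "rlddm_prior")
}

prior_logd <- function(p, x) p$ld(x)
prior_sample <- function(p, n = 1) p$r(n)

# Subject-level distributions around group mean mu with group SD sigma.
# "gamma": Gamma parameterized by (mean = mu, sd = sigma); "normal": Normal.
subj_logd <- function(kind, x, mu, sd) {
  if (sd <= 0) return(-Inf)
  if (kind == "gamma") {
    if (mu <= 0) return(-Inf)
    shape <- (mu / sd)^2
    rate <- mu / sd^2
    sum(ifelse(x > 0, stats::dgamma(x, shape = shape, rate = rate, log = TRUE), -Inf))
  } else {
    sum(stats::dnorm(x, mu, sd, log = TRUE))
  }
}

subj_sample <- function(kind, n, mu, sd) {
  if (kind == "gamma") {
    shape <- (max(mu, 1e-6) / sd)^2
    rate <- max(mu, 1e-6) / sd^2
    stats::rgamma(n, shape = shape, rate = rate)
  } else {
    stats::rnorm(n, mu, sd)
  }
}

#' Default hierarchical priors
#'
#' Returns the default prior structure: for each parameter family a
#' group-mean prior, a group-SD prior, the subject-level distribution, and
#' the transform linking the sampled (unconstrained) scale to the parameter
#' scale:
#'
#' * threshold `a`: mean ~ Gamma(mean 1.5, rate 0.75), SD ~ HalfNormal(0.1),
#'   subjects ~ Gamma(mean, SD); identity.
#' * drift scaling `v`: mean ~ Normal(2, 3), SD ~ HalfNormal(2),
#'   subjects ~ Normal; identity.
#' * non-decision time `t`: mean ~ Gamma(mean 0.4, rate 0.2),
#'   SD ~ HalfNormal(1), subjects ~ Normal; identity (support enforced by
#'   the likelihood).
#' * starting point `z`: mean ~ Normal(0.5, 0.5), SD ~ HalfNormal(0.5),
#'   subjects ~ Normal on the unconstrained scale; inverse logit.
#' * learning rate `alpha` (and `alpha_neg`): mean ~ Normal(0, 3),
#'   SD ~ HalfNormal(2), subjects ~ Normal on the unconstrained scale;
#'   inverse logit.
#' * between-trial variabilities (group-only): `sv` ~ HalfNormal(2),
#'   `st` ~ HalfNormal(0.3), `sz` ~ Beta(1, 3).
#' * regression slopes: mean ~ Normal(0, 2), SD = the target parameter's
#'   group-SD prior; regression intercepts use the target's group-mean prior.
#'
#' @return A named list of family prior specifications; pass (possibly
#'   modified) to [build_model()].
#' @export
default_priors <- function() {
  list(
    a = list(mu = prior_gamma_mean_rate(1.5, 0.75), sd = prior_halfnormal(0.1),
             subj = "gamma", transform = "identity"),
    v = list(mu = prior_normal(2, 3), sd = prior_halfnormal(2),
             subj = "normal", transform = "identity"),
    t = list(mu = prior_gamma_mean_rate(0.4, 0.2), sd = prior_halfnormal(1),
             subj = "normal", transform = "identity"),
    z = list(mu = prior_normal(0.5, 0.5), sd = prior_halfnormal(0.5),
             subj = "normal", transform = "invlogit"),
    alpha = list(mu = prior_normal(0, 3), sd = prior_halfnormal(2),
                 subj = "normal", transform = "invlogit"),
    alpha_neg = list(mu = prior_normal(0, 3), sd = prior_halfnormal(2),
                     subj = "normal", transform = "invlogit"),
    sv = prior_halfnormal(2),
    st = prior_halfnormal(0.3),
    sz = prior_beta(1, 3),
    slope = list(mu = prior_normal(0, 2))
  )
}
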