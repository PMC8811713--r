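# Wiener first-passage-time density and the composed RLDDM / softmax-RL
# log-likelihoods. The diffusion coefficient is fixed at 1 (the scaling
# convention in which all parameter values here are expressed).

check_ddm_params <- function(a, t, z, sv, st, sz) {
  if (any(a <= 0)) abort_domain("decision threshold a must be > 0")
  if (any(t < 0)) abort_domain("non-decision time t must be >= 0")
  if (any(z <= 0 | z >= 1)) abort_domain("starting point z must be in (0, 1)")
  if (sv < 0 || st < 0 || sz < 0)
    abort_domain("between-trial variabilities sv, st, sz must be >= 0")
  if (sz > 0 && any(z - sz / 2 <= 0 | z + sz / 2 >= 1))
    abort_domain("z +/- sz/2 must stay inside (0, 1)")
  if (st > 0 && any(t - st / 2 < 0))
    abort_domain("t - st/2 must be >= 0")
  invisible(TRUE)
}

#' Wiener first-passage-time density
#'
#' Joint density of hitting the named boundary at time `rt`, for a diffusion
#' starting at relative position `z` between boundaries 0 and `a`, with drift
#' `v` and non-decision time `t` (diffusion coefficient 1). Evaluated with
#' the Navarro–Fuss series approximation, switching between the small-time
#' and large-time expansions by their term-count criterion at absolute error
#' `tol`. Between-trial drift variability `sv` uses the closed-form Gaussian
#' mixture; uniform non-decision-time (`st`) and starting-point (`sz`) ranges
#' are integrated by 11-node Gauss–Legendre quadrature. The density is 0 for
#' `rt <= t`.
#'
#' @param rt Response time(s) in seconds.
#' @param boundary `"upper"`/`"lower"` (or 1/0), recycled against `rt`.
#' @param a Decision threshold (> 0).
#' @param v Drift rate (may be vectorized per trial).
#' @param t Non-decision time in seconds (>= 0).
#' @param z Relative starting point in (0, 1).
#' @param sv,st,sz Between-trial standard deviation of drift, and ranges of
#'   uniform non-decision-time and starting-point perturbations (all >= 0).
#' @param tol Absolute error bound of the series approximation.
#' @return Density values, same length as `rt`.
#' @examples
#' wfpt_pdf(0.8, "upper", a = 2, v = 1, t = 0.3)
#' @export
wfpt_pdf <- function(rt, boundary, a, v, t, z = 0.5,
                     sv = 0, st = 0, sz = 0, tol = 1e-4) {
  if (tol <= 0) abort_domain("tol must be > 0")
  check_ddm_params(a, t, z, sv, st, sz)
  up <- boundary_code(boundary)
  n <- max(length(rt), length(up))
  wfpt_pdf_cpp(rep_len(as.numeric(rt), n), rep_len(up, n),
               as.numeric(a), as.numeric(v), as.numeric(t), as.numeric(z),
               sv, st, sz, tol)
}

boundary_code <- function(boundary) {
  if (is.character(boundary)) {
    if (!all(boundary %in% c("upper", "lower")))
      abort_domain("boundary must be 'upper'/'lower' or 1/0")
    as.integer(boundary == "upper")
  } else {
    if (!all(boundary %in% c(0, 1)))
      abort_domain("boundary must be 'upper'/'lower' or 1/0")
    as.integer(boundary)
  }
}

#' Probability of absorption at the upper boundary
#'
#' Closed form for the pure diffusion (no between-trial variability):
#' `(1 - exp(-2 a v z)) / (1 - exp(-2 a v))`, with the driftless limit equal
#' to `z`. For `z = 0.5` this reduces to a two-option softmax with inverse
#' temperature `a * v` — the sense in which a DDM that ignores RT is a
#' softmax choice rule.
#'
#' @param a Decision threshold (> 0).
#' @param v Drift rate.
#' @param z Relative starting point in (0, 1).
#' @return Probability of hitting the upper boundary.
#' @export
choice_prob_upper <- function(a, v, z = 0.5) {
  check_ddm_params(a, 0, z, 0, 0, 0)
  av <- a * v
  out <- ifelse(abs(av) < 1e-12, z, expm1(-2 * av * z) / expm1(-2 * av))
  as.numeric(out)
}

#' RLDDM log-likelihood of a trial table
#'
#' For each subject-by-condition block (in file order): evolves the two
#' expected values by the delta rule, sets the trial drift rate to
#' `(q_upper - q_lower) * v_scale`, and accumulates the log wfpt density of
#' the observed (response, rt) pair. One parameter set is applied to the
#' whole table (see [build_model()] for hierarchical, per-subject fits).
#'
#' Any trial with `rt <= t` (or a non-positive density) yields `-Inf`,
#' flagged via the `"nonfinite"` attribute; an MCMC sampler treats such a
#' state as rejected.
#'
#' @param table A `trial_table`.
#' @param a,t,z Decision threshold, non-decision time, starting point.
#' @param v_scale Drift scaling parameter.
#' @param alpha,alpha_neg,dual Learning rate(s) on the probability scale,
#'   see [compute_q_trajectory()].
#' @param sv,st,sz Between-trial variability parameters.
#' @param tol Absolute error bound for the wfpt series.
#' @return Scalar log-likelihood.
#' @export
rlddm_loglik <- function(table, a, v_scale, t, alpha, z = 0.5,
                         alpha_neg = NULL, dual = FALSE,
                         sv = 0, st = 0, sz = 0, tol = 1e-4) {
  check_ddm_params(a, t, z, sv, st, sz)
  if (any(alpha < 0 | alpha > 1)) abort_domain("alpha must be in [0, 1]")
  if (dual && is.null(alpha_neg)) abort_domain("alpha_neg required when dual = TRUE")
  ll <- rlddm_block_loglik_cpp(
    as.numeric(table$rt), as.integer(table$response),
    as.numeric(table$feedback), block_index(table), as.numeric(table$q_init),
    as.numeric(a), as.numeric(v_scale), as.numeric(t), as.numeric(z),
    alpha, if (dual) alpha_neg else alpha, dual, sv, st, sz, tol, 1e-3)
  if (!is.finite(ll)) attr(ll, "nonfinite") <- TRUE
  ll
}

#' Softmax-RL log-likelihood (choice only, no response times)
#'
#' Sum over trials of the log softmax probability of the observed response,
#' with expected values updated by the delta rule. This is the RT-free
#' counterpart of [rlddm_loglik()]; the table may lack an `rt` column.
#'
#' @param table A `trial_table` (validated with `require_rt = FALSE` if it
#'   has no `rt` column).
#' @param beta Inverse temperature (>= 0).
#' @inheritParams rlddm_loglik
#' @return Scalar log-likelihood.
#' @export
rl_softmax_loglik <- function(table, alpha, beta, alpha_neg = NULL,
                              dual = FALSE) {
  if (any(beta < 0)) abort_domain("beta must be >= 0")
  if (any(alpha < 0 | alpha > 1)) abort_domain("alpha must be in [0, 1]")
  if (dual && is.null(alpha_neg)) abort_domain("alpha_neg required when dual = TRUE")
  rl_softmax_block_loglik_cpp(
    as.integer(table$response), as.numeric(table$feedback),
    block_index(table), as.numeric(table$q_init), as.numeric(beta),
    alpha, if (dual) alpha_neg else alpha, dual)
}
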