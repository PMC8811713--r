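# Delta-rule value learning, softmax choice, and drift-rate construction.

#' Inverse logit
#'
#' `exp(x) / (1 + exp(x))`, overflow-safe. Learning-rate and starting-point
#' parameters are sampled on the unconstrained scale and mapped to (0, 1)
#' through this transform.
#'
#' @param x Numeric vector.
#' @return Values in (0, 1).
#' @examples
#' invlogit(0)      # 0.5
#' invlogit(-2.32)  # ~0.09, a typical posterior-mean learning rate
#' @export
invlogit <- function(x) stats::plogis(x)

#' Logit (inverse of [invlogit()])
#' @param p Numeric vector in (0, 1).
#' @export
logit <- function(p) stats::qlogis(p)

#' Delta-rule update of an expected value
#'
#' `Q <- Q + alpha * (reward - Q)`: the expectation moves toward the received
#' reward in proportion to the reward prediction error.
#'
#' @param q Current expected value.
#' @param reward Received reward.
#' @param alpha Learning rate in \[0, 1\].
#' @return Updated expected value.
#' @examples
#' update_q(0.5, 1, 0.1)  # 0.55
#' @export
update_q <- function(q, reward, alpha) {
  if (any(alpha < 0 | alpha > 1)) abort_domain("alpha must be in [0, 1]")
  q + alpha * (reward - q)
}

#' Q-value trajectory of one subject-by-condition block
#'
#' Sequentially applies the delta rule over an ordered block of trials.
#' Only the chosen option's expectation is updated; the other option's value
#' is carried forward unchanged. With `dual = TRUE` the learning rate depends
#' on the sign of the reward prediction error (`alpha` for positive, and
#' `alpha_neg` for negative; a prediction error of exactly zero uses the
#' positive-branch `alpha`).
#'
#' @param block Ordered trials of a single subject-by-condition block: a
#'   `trial_table` subset (or any data frame with `response`, `feedback`,
#'   `q_init` columns).
#' @param alpha Learning rate in \[0, 1\] (positive prediction errors when
#'   `dual`).
#' @param alpha_neg Learning rate for negative prediction errors (only used
#'   when `dual = TRUE`).
#' @param dual Use separate learning rates by prediction-error sign.
#' @return A data frame of class `q_trajectory` with columns `q_upper`,
#'   `q_lower`, `rpe` — the expectations each decision was based on and the
#'   prediction error realised on that trial.
#' @export
compute_q_trajectory <- function(block, alpha, alpha_neg = NULL, dual = FALSE) {
  if (nrow(block) == 0) abort_precondition("block must be non-empty")
  if (!"q_init" %in% names(block)) abort_schema("block lacks a q_init column")
  if (length(unique(paste(block$subj_idx, block$split_by))) > 1)
    abort_precondition("block must contain a single subject-by-condition block")
  if (any(alpha < 0 | alpha > 1)) abort_domain("alpha must be in [0, 1]")
  if (dual) {
    if (is.null(alpha_neg)) abort_domain("alpha_neg required when dual = TRUE")
    if (any(alpha_neg < 0 | alpha_neg > 1)) abort_domain("alpha_neg must be in [0, 1]")
  }
  m <- q_trajectory_cpp(as.integer(block$response), as.numeric(block$feedback),
                        block$q_init[1], alpha,
                        if (dual) alpha_neg else alpha, dual)
  structure(data.frame(q_upper = m[, 1], q_lower = m[, 2], rpe = m[, 3]),
            class = c("q_trajectory", "data.frame"))
}

#' Softmax probability of choosing the upper-boundary option
#'
#' Two-option softmax with inverse temperature `beta`, computed on the
#' difference of expected values so it is overflow-safe.
#'
#' @param q_upper,q_lower Expected values of the two options.
#' @param beta Inverse temperature, `>= 0`. Zero yields indifference (0.5);
#'   large values approach deterministic exploitation.
#' @return Probability of the upper option.
#' @export
softmax_prob <- function(q_upper, q_lower, beta) {
  if (any(beta < 0)) abort_domain("beta must be >= 0")
  stats::plogis(beta * (q_upper - q_lower))
}

#' Trial drift rate from expected values
#'
#' The RLDDM drift rate is the difference in expected values scaled by the
#' drift scaling parameter: `(q_upper - q_lower) * v_scale`.
#'
#' @param q_upper,q_lower Expected values of the two options.
#' @param v_scale Drift scaling parameter (plays the exploit/explore role the
#'   inverse temperature plays in the softmax).
#' @return Drift rate (signed real).
#' @export
drift_rate <- function(q_upper, q_lower, v_scale) {
  (q_upper - q_lower) * v_scale
}
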