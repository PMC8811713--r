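# Forward generation: DDM first-passage trials, RLDDM agents on
# probabilistic-selection-task schedules, and covariate-augmented datasets.

#' Probabilistic selection task schedule
#'
#' The learning-phase structure of the probabilistic selection task: three
#' two-option conditions in which the better option (tied to the upper
#' boundary, `response = 1`) is rewarded with probability 0.8, 0.7 and 0.6
#' and the worse option with 0.2, 0.3 and 0.4 respectively. Feedback is
#' binary (1 reward, 0 non-reward) and expectations start at `q_init`.
#'
#' @param n_trials Trials per condition.
#' @param conditions Data frame with columns `label`, `p_upper`, `p_lower`
#'   (reward probabilities in \[0, 1\]).
#' @param q_init Initial expected value for both options.
#' @return A `task_schedule`.
#' @export
pst_schedule <- function(n_trials = 60,
                         conditions = data.frame(
                           label = c("AB", "CD", "EF"),
                           p_upper = c(0.8, 0.7, 0.6),
                           p_lower = c(0.2, 0.3, 0.4)),
                         q_init = 0.5) {
  if (any(n_trials < 1)) abort_domain("n_trials must be >= 1")
  if (any(conditions$p_upper < 0 | conditions$p_upper > 1 |
          conditions$p_lower < 0 | conditions$p_lower > 1))
    abort_domain("reward probabilities must be in [0, 1]")
  conditions$n_trials <- rep_len(n_trials, nrow(conditions))
  structure(list(conditions = conditions, q_init = q_init),
            class = "task_schedule")
}

#' Simulate first-passage trials of the drift diffusion process
#'
#' Euler–Maruyama simulation (step `dt`, diffusion coefficient 1) with a
#' Brownian-bridge crossing check each step; between-trial variability is
#' applied by perturbing `v` (normal), `t` and `z` (uniform) before each
#' walk. Walks not absorbed within `max_t` seconds of decision time are
#' redrawn.
#'
#' @param n Number of trials.
#' @param a,v,t,z DDM parameters; `v` may be a per-trial vector.
#' @param sv,st,sz Between-trial variability parameters.
#' @param dt Euler step in seconds.
#' @param max_t Decision-time horizon in seconds.
#' @return Data frame with columns `response` (1 = upper) and `rt`.
#' @export
sample_ddm_trial <- function(n = 1, a, v, t, z = 0.5, sv = 0, st = 0, sz = 0,
                             dt = 1e-4, max_t = 20) {
  check_ddm_params(a, t, z, sv, st, sz)
  if (dt <= 0 || max_t <= 0) abort_domain("dt and max_t must be > 0")
  sample_ddm_trials_cpp(as.integer(n), a, as.numeric(v), t, z, sv, st, sz,
                        dt, max_t)
}

# Draw subject-level parameter values around group means.
draw_subject_params <- function(n, group, sds, alpha_scale) {
  a <- redraw_until(n, function(k) stats::rnorm(k, group$a, sds$a),
                    function(x) x > 0)
  t <- redraw_until(n, function(k) stats::rnorm(k, group$t, sds$t),
                    function(x) x >= 0)
  v <- stats::rnorm(n, group$v, sds$v)
  if (alpha_scale == "unconstrained") {
    if (group$alpha <= 0 || group$alpha >= 1)
      abort_domain("group alpha must be inside (0, 1) on the unconstrained scale; use alpha_scale = 'probability' for boundary values")
    # SD stated on the probability scale, converted by the delta method
    mu_u <- logit(group$alpha)
    sd_u <- sds$alpha / (group$alpha * (1 - group$alpha))
    alpha <- invlogit(stats::rnorm(n, mu_u, sd_u))
  } else {
    alpha <- redraw_until(n, function(k) stats::rnorm(k, group$alpha, sds$alpha),
                          function(x) x >= 0 & x <= 1)
  }
  list(a = a, v = v, t = t, alpha = alpha)
}

redraw_until <- function(n, rfun, ok, max_tries = 100) {
  x <- rfun(n)
  for (i in seq_len(max_tries)) {
    bad <- !ok(x)
    if (!any(bad)) return(x)
    x[bad] <- rfun(sum(bad))
  }
  abort_domain("could not draw subject parameters inside their support")
}

#' Simulate a hierarchical RLDDM dataset
#'
#' Draws subject parameters from normal distributions around the group
#' means (learning rates on the unconstrained scale by default, with the
#' stated SD converted from the probability scale by the delta method), then
#' simulates every subject on the task schedule: each trial's drift rate is
#' the scaled difference of the running expected values, the (choice, rt)
#' pair is a first-passage sample, feedback is Bernoulli under the chosen
#' option's reward probability, and the chosen option's expectation is
#' updated by the delta rule.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param schedule A [pst_schedule()].
#' @param group Named list of group means (`a`, `v`, `t`, `alpha`).
#' @param sds Named list of subject-level SDs on the same scales.
#' @param z Starting point (fixed across subjects).
#' @param dual,alpha_neg_group,alpha_neg_sd Separate negative-error learning
#'   rate (group mean and SD) when `dual = TRUE`.
#' @param alpha_scale Scale on which subject learning rates are drawn:
#'   `"unconstrained"` (default) or `"probability"`.
#' @param sv,st,sz Between-trial variabilities used in generation.
#' @param seed Optional integer seed.
#' @param dt,max_t Euler–Maruyama controls, see [sample_ddm_trial()].
#' @return A `trial_table` with attribute `"true_params"` (the subject
#'   parameter draws).
#' @export
simulate_rlddm_dataset <- function(n_subjects,
                                   schedule = pst_schedule(),
                                   group = list(a = 2, v = 2.25, t = 0.4,
                                                alpha = 0.3),
                                   sds = list(a = 0.1, v = 0.25, t = 0.02,
                                              alpha = 0.1),
                                   z = 0.5, dual = FALSE,
                                   alpha_neg_group = NULL, alpha_neg_sd = NULL,
                                   alpha_scale = c("unconstrained", "probability"),
                                   sv = 0, st = 0, sz = 0,
                                   seed = NULL, dt = 1e-4, max_t = 20) {
  alpha_scale <- match.arg(alpha_scale)
  if (!is.null(seed)) set.seed(seed)
  pars <- draw_subject_params(n_subjects, group, sds, alpha_scale)
  if (dual) {
    stopifnot(!is.null(alpha_neg_group))
    g2 <- list(a = 1, v = 0, t = 0, alpha = alpha_neg_group)
    s2 <- list(a = 1, v = 0, t = 1, alpha = alpha_neg_sd %||% 0.1)
    pars$alpha_neg <- draw_subject_params(n_subjects, g2, s2, alpha_scale)$alpha
  }
  out <- vector("list", n_subjects * nrow(schedule$conditions))
  k <- 0
  for (j in seq_len(n_subjects)) {
    for (ci in seq_len(nrow(schedule$conditions))) {
      cond <- schedule$conditions[ci, ]
      blk <- sim_rlddm_block_cpp(cond$n_trials, pars$a[j], pars$v[j],
                                 pars$t[j], z, pars$alpha[j],
                                 if (dual) pars$alpha_neg[j] else pars$alpha[j],
                                 dual, schedule$q_init,
                                 cond$p_upper, cond$p_lower,
                                 sv, st, sz, dt, max_t)
      k <- k + 1
      out[[k]] <- data.frame(rt = blk$rt, response = blk$response,
                             split_by = cond$label, subj_idx = j - 1L,
                             feedback = blk$feedback,
                             q_init = schedule$q_init)
    }
  }
  tab <- validate_trials(do.call(rbind, out))
  attr(tab, "true_params") <- pars
  tab
}

#' Simulate an RLDDM dataset with a trial-wise threshold covariate
#'
#' Generates data for the regression-recovery demonstration: a trial-wise
#' regressor is drawn from Normal(0, 1) and each trial's decision threshold
#' equals the subject's baseline plus `coef` times the regressor (floored at
#' a small positive bound). All other parameters behave as in
#' [simulate_rlddm_dataset()]. The regressor is stored in the returned table
#' under `covariate_name`.
#'
#' @param n_subjects Number of subjects.
#' @param schedule A [pst_schedule()].
#' @param baseline Baseline threshold (the regression intercept), a single
#'   fixed value shared by all subjects in the demonstration design.
#' @param coef Covariate coefficient, identical for all subjects.
#' @param baseline_sd Optional subject-level SD of the baseline threshold
#'   (0: fixed baseline, the demonstration default).
#' @param covariate_name Column name for the stored regressor.
#' @param group,sds Group means/SDs of the remaining parameters
#'   (`v`, `t`, `alpha`).
#' @param z,seed,dt,max_t As in [simulate_rlddm_dataset()].
#' @return A `trial_table` with the covariate column and a `"true_params"`
#'   attribute.
#' @export
simulate_regression_dataset <- function(n_subjects = 30,
                                        schedule = pst_schedule(),
                                        baseline = 1, coef = 0.2,
                                        baseline_sd = 0,
                                        covariate_name = "neural",
                                        group = list(v = 2.25, t = 0.3,
                                                     alpha = 0.3),
                                        sds = list(v = 0.25, t = 0.02,
                                                   alpha = 0.1),
                                        z = 0.5, seed = NULL,
                                        dt = 1e-4, max_t = 20) {
  if (!is.finite(coef)) abort_domain("coef must be finite")
  if (!is.null(seed)) set.seed(seed)
  g <- list(a = baseline, v = group$v, t = group$t, alpha = group$alpha)
  s <- list(a = baseline_sd, v = sds$v, t = sds$t, alpha = sds$alpha)
  pars <- draw_subject_params(n_subjects, g, s, "unconstrained")
  out <- vector("list", n_subjects * nrow(schedule$conditions))
  k <- 0
  for (j in seq_len(n_subjects)) {
    for (ci in seq_len(nrow(schedule$conditions))) {
      cond <- schedule$conditions[ci, ]
      x <- stats::rnorm(cond$n_trials)
      a_trial <- pmax(pars$a[j] + coef * x, 1e-3)
      blk <- sim_rlddm_block_cpp(cond$n_trials, a_trial, pars$v[j],
                                 pars$t[j], z, pars$alpha[j], pars$alpha[j],
                                 FALSE, schedule$q_init,
                                 cond$p_upper, cond$p_lower,
                                 0, 0, 0, dt, max_t)
      k <- k + 1
      df <- data.frame(rt = blk$rt, response = blk$response,
                       split_by = cond$label, subj_idx = j - 1L,
                       feedback = blk$feedback, q_init = schedule$q_init)
      df[[covariate_name]] <- x
      out[[k]] <- df
    }
  }
  tab <- validate_trials(do.call(rbind, out))
  attr(tab, "true_params") <- c(pars, list(coef = coef))
  tab
}
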