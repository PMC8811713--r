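# Parameter-recovery harness: simulate -> fit -> compare group parameters.

#' Parameter-recovery design
#'
#' The default grid crosses three plausible values of each group parameter —
#' threshold `a` in \{1.5, 2.0, 2.5\}, non-decision time `t` in
#' \{0.3, 0.4, 0.5\}, learning rate `alpha` in \{0.15, 0.3, 0.45\} and drift
#' scaling `v` in \{1.5, 2.25, 3.0\} — giving 81 datasets, each with 40
#' synthetic subjects performing 60 trials in each of the three
#' probabilistic-selection-task conditions. Subject-level SDs default to
#' `a` 0.1, `t` 0.02, `alpha` 0.1, `v` 0.25.
#'
#' @param a,t,alpha,v Group-mean values to cross.
#' @param sds Subject-level SDs.
#' @param n_subjects Subjects per dataset.
#' @param n_trials Trials per condition.
#' @return A `recovery_design`: the full-factorial grid plus settings.
#' @export
recovery_design <- function(a = c(1.5, 2.0, 2.5), t = c(0.3, 0.4, 0.5),
                            alpha = c(0.15, 0.3, 0.45), v = c(1.5, 2.25, 3.0),
                            sds = list(a = 0.1, t = 0.02, alpha = 0.1,
                                       v = 0.25),
                            n_subjects = 40, n_trials = 60) {
  grid <- expand.grid(a = a, t = t, alpha = alpha, v = v,
                      KEEP.OUT.ATTRS = FALSE)
  structure(list(grid = grid, sds = sds, n_subjects = n_subjects,
                 n_trials = n_trials),
            class = "recovery_design")
}

#' Run a parameter-recovery study
#'
#' For every grid cell of the design: simulate a dataset, fit the default
#' hierarchical RLDDM, and record the posterior mean of each group parameter
#' against its generating value. Learning rates are compared on the
#' probability scale (posterior mean of the inverse-logit draws).
#' Individual fit failures are recorded in the report, not fatal.
#'
#' @param design A [recovery_design()].
#' @param cells Optional integer subset of grid rows to run.
#' @param n_samples,burn Sampler settings per fit.
#' @param seed Base seed; cell `i` uses `seed + i`.
#' @param alpha_scale Passed to [simulate_rlddm_dataset()].
#' @return Tidy data frame: one row per (cell, parameter) with columns
#'   `cell, parameter, truth, estimate, abs_error, n_subjects, n_trials,
#'   status`.
#' @export
run_recovery <- function(design = recovery_design(), cells = NULL,
                         n_samples = 1500, burn = 500, seed = 1,
                         alpha_scale = "unconstrained") {
  if (!inherits(design, "recovery_design")) abort_config("need a recovery_design")
  idx <- cells %||% seq_len(nrow(design$grid))
  rows <- list()
  for (i in idx) {
    cell <- design$grid[i, ]
    res <- tryCatch({
      dat <- simulate_rlddm_dataset(
        design$n_subjects, pst_schedule(design$n_trials),
        group = list(a = cell$a, v = cell$v, t = cell$t, alpha = cell$alpha),
        sds = design$sds, alpha_scale = alpha_scale, seed = seed + i)
      fit <- sample_posterior(build_model(dat), n_samples = n_samples,
                              burn = burn, seed = seed + i)
      m <- pooled_draws(fit)
      est <- c(a = mean(m[, "a"]), t = mean(m[, "t"]), v = mean(m[, "v"]),
               alpha = mean(invlogit(m[, "alpha"])))
      list(est = est, status = "ok")
    }, error = function(e) list(est = c(a = NA, t = NA, v = NA, alpha = NA),
                                status = conditionMessage(e)))
    truth <- c(a = cell$a, t = cell$t, v = cell$v, alpha = cell$alpha)
    rows[[length(rows) + 1]] <- data.frame(
      cell = i, parameter = names(truth), truth = as.numeric(truth),
      estimate = as.numeric(res$est[names(truth)]),
      abs_error = abs(as.numeric(res$est[names(truth)]) - as.numeric(truth)),
      n_subjects = design$n_subjects, n_trials = design$n_trials,
      status = res$status, row.names = NULL)
  }
  do.call(rbind, rows)
}
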