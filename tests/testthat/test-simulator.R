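test_that("first-passage sampling: symmetry, closed-form agreement, support", {
  set.seed(51)
  s <- sample_ddm_trial(4000, a = 1.5, v = 0, t = 0.3, z = 0.5)
  p <- mean(s$response)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 4000))
  expect_true(all(s$rt > 0.3))

  s2 <- sample_ddm_trial(4000, a = 1, v = 2, t = 0.3, z = 0.5)
  p_theory <- choice_prob_upper(1, 2, 0.5)
  expect_lt(abs(mean(s2$response) - p_theory),
            3 * sqrt(p_theory * (1 - p_theory) / 4000))
})

test_that("simulated first-passage times match the wfpt density (KS)", {
  set.seed(53)
  n <- 8000
  s <- sample_ddm_trial(n, a = 1.6, v = 1.2, t = 0.25, z = 0.45)
  ks <- signed_ks_stat(s$response, s$rt,
                       function(x, b) wfpt_pdf(x, b, 1.6, 1.2, 0.25, 0.45,
                                               tol = 1e-6), t = 0.25)
  expect_lt(ks, 1.6276 / sqrt(n))
})

test_that("between-trial variability propagates into the generative process", {
  set.seed(55)
  n <- 6000
  s <- sample_ddm_trial(n, a = 1.4, v = 1, t = 0.3, z = 0.5,
                        sv = 0.8, st = 0.1, sz = 0.2)
  expect_true(all(s$rt > 0.25))  # t - st/2
  ks <- signed_ks_stat(s$response, s$rt,
                       function(x, b) wfpt_pdf(x, b, 1.4, 1, 0.3, 0.5,
                                               sv = 0.8, st = 0.1, sz = 0.2,
                                               tol = 1e-6), t = 0.25)
  expect_lt(ks, 1.6276 / sqrt(n))
})

test_that("identical seeds give identical datasets", {
  d1 <- simulate_rlddm_dataset(3, pst_schedule(12), seed = 57)
  d2 <- simulate_rlddm_dataset(3, pst_schedule(12), seed = 57)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_identical(attr(d1, "true_params"), attr(d2, "true_params"))
})

test_that("feedback follows the programmed reward schedule", {
  # a zero learning rate keeps choices random, sampling both options often
  d <- simulate_rlddm_dataset(
    1, pst_schedule(800, conditions = data.frame(label = "AB", p_upper = 0.8,
                                                 p_lower = 0.2)),
    group = list(a = 2, v = 2, t = 0.3, alpha = 0),
    sds = list(a = 0, v = 0, t = 0, alpha = 0),
    alpha_scale = "probability", seed = 59)
  up <- d$response == 1
  p_up <- mean(d$feedback[up])
  p_lo <- mean(d$feedback[!up])
  expect_lt(abs(p_up - 0.8), 3 * sqrt(0.8 * 0.2 / sum(up)))
  expect_lt(abs(p_lo - 0.2), 3 * sqrt(0.2 * 0.8 / sum(!up)))
  # alpha = 0: expectations never separate, so choices stay at chance
  expect_lt(abs(mean(d$response) - 0.5), 3 * sqrt(0.25 / nrow(d)))
})

test_that("easier reward contrasts yield higher late-trial accuracy", {
  acc <- matrix(NA_real_, 3, 2)
  for (i in 1:3) {
    d <- simulate_rlddm_dataset(10, pst_schedule(40), seed = 60 + i)
    late <- as.data.frame(d)
    late$trial <- stats::ave(seq_len(nrow(late)),
                             paste(late$subj_idx, late$split_by),
                             FUN = seq_along)
    late <- late[late$trial > 20, ]
    acc[i, 1] <- mean(late$response[late$split_by == "AB"])
    acc[i, 2] <- mean(late$response[late$split_by == "EF"])
  }
  expect_gt(mean(acc[, 1]), mean(acc[, 2]))
})

test_that("the regression generator injects the stated threshold structure", {
  d <- simulate_regression_dataset(4, pst_schedule(40), baseline = 1,
                                   coef = 0.2, seed = 61)
  expect_true("neural" %in% names(d))
  tp <- attr(d, "true_params")
  # within-subject SD of realized trial thresholds ~ |coef| * sd(neural)
  for (j in unique(d$subj_idx)) {
    sub <- d[d$subj_idx == j, ]
    a_trial <- tp$a[j + 1] + tp$coef * sub$neural
    expect_equal(sd(a_trial), 0.2 * sd(sub$neural), tolerance = 1e-12)
  }
  expect_equal(sd(d$neural), 1, tolerance = 0.15)
  # a zero coefficient degenerates to the plain generator interface
  d0 <- simulate_regression_dataset(2, pst_schedule(10), coef = 0, seed = 62)
  expect_s3_class(d0, "trial_table")
})

test_that("task schedules validate their probabilities and sizes", {
  expect_error(pst_schedule(0), class = "rlddm_domain_error")
  expect_error(pst_schedule(10, conditions = data.frame(label = "A",
                                                        p_upper = 1.2,
                                                        p_lower = 0.1)),
               class = "rlddm_domain_error")
  sch <- pst_schedule(25)
  expect_equal(sch$conditions$n_trials, rep(25, 3))
  expect_equal(sch$conditions$p_upper, c(0.8, 0.7, 0.6))
})

test_that("a reduced recovery run reports the full group-parameter contract", {
  design <- recovery_design(a = 2, t = 0.35, alpha = 0.3, v = 2.25,
                            n_subjects = 4, n_trials = 12)
  expect_equal(nrow(recovery_design()$grid), 81)
  rep <- run_recovery(design, n_samples = 150, burn = 60, seed = 63)
  expect_equal(nrow(rep), 4)
  expect_setequal(rep$parameter, c("a", "t", "v", "alpha"))
  expect_equal(rep$truth[rep$parameter == "a"], 2)
  expect_equal(rep$truth[rep$parameter == "alpha"], 0.3)
  expect_true(all(rep$status == "ok"))
  expect_true(all(is.finite(rep$abs_error)))
})

test_that("recovery error shrinks with more data", {
  errs <- sapply(1:2, function(seed) {
    small <- run_recovery(recovery_design(a = 2, t = 0.35, alpha = 0.3,
                                          v = 2.25, n_subjects = 3,
                                          n_trials = 8),
                          n_samples = 200, burn = 80, seed = 70 + seed)
    big <- run_recovery(recovery_design(a = 2, t = 0.35, alpha = 0.3,
                                        v = 2.25, n_subjects = 8,
                                        n_trials = 40),
                        n_samples = 200, burn = 80, seed = 70 + seed)
    c(small = mean(small$abs_error[small$parameter %in% c("a", "t")]),
      big = mean(big$abs_error[big$parameter %in% c("a", "t")]))
  })
  expect_lt(mean(errs["big", ]), mean(errs["small", ]))
})
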