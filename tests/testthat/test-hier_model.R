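test_that("formula parsing: targets, expansion, intercept rules", {
  cols <- c("neural", "stn", "theta", "presma")
  r <- parse_formula("a ~ neural", cols)
  expect_s3_class(r, "regression_spec")
  expect_identical(r$target, "a")
  expect_identical(r$terms, "neural")
  expect_true(r$intercept)

  r2 <- parse_formula("a ~ stn*theta*conflict + presma*conflict", cols)
  expect_setequal(r2$terms,
                  c("stn", "theta", "conflict", "presma",
                    "stn:theta", "stn:conflict", "theta:conflict",
                    "conflict:presma", "stn:theta:conflict"))
  expect_true(r2$intercept)

  r3 <- parse_formula("a ~ 0 + neural", cols)
  expect_false(r3$intercept)
  expect_identical(r3$terms, "neural")

  r4 <- parse_formula("a ~ stn:theta", cols)
  expect_identical(r4$terms, "stn:theta")

  expect_error(parse_formula("banana ~ neural", cols),
               "banana", class = "rlddm_parse_error")
  expect_error(parse_formula("a ~ bogus", cols),
               "bogus", class = "rlddm_parse_error")
  expect_error(parse_formula("a + neural", cols), class = "rlddm_parse_error")
})

test_that("default priors reproduce the stated hierarchical structure", {
  p <- default_priors()
  expect_equal(p$a$mu$analytic_mean, 1.5)
  expect_equal(p$a$mu$rate, 0.75)
  expect_equal(p$a$sd$sigma, 0.1)
  expect_identical(p$a$subj, "gamma")
  expect_equal(p$v$mu$mean, 2); expect_equal(p$v$mu$sd, 3)
  expect_equal(p$t$mu$analytic_mean, 0.4); expect_equal(p$t$mu$rate, 0.2)
  expect_equal(p$z$mu$mean, 0.5); expect_equal(p$z$mu$sd, 0.5)
  expect_identical(p$z$transform, "invlogit")
  expect_equal(p$alpha$mu$mean, 0); expect_equal(p$alpha$mu$sd, 3)
  expect_identical(p$alpha$transform, "invlogit")
  expect_equal(p$sv$sigma, 2)
  expect_equal(p$st$sigma, 0.3)
  expect_equal(p$sz$shape1, 1); expect_equal(p$sz$shape2, 3)
})

test_that("prior samplers match their analytic means", {
  set.seed(31)
  n <- 2e4
  p <- default_priors()
  draws <- list(a_mu = p$a$mu, t_mu = p$t$mu, v_mu = p$v$mu,
                sv = p$sv, st = p$st, sz = p$sz)
  for (nm in names(draws)) {
    pr <- draws[[nm]]
    x <- rlddm:::prior_sample(pr, n)
    se <- sd(x) / sqrt(n)
    expect_lt(abs(mean(x) - pr$analytic_mean), 4 * se)
  }
})

test_that("default model on 2 subjects exposes the expected free parameters", {
  d <- simulate_rlddm_dataset(2, pst_schedule(6), seed = 2)
  m <- build_model(d)
  expect_setequal(m$state_names,
                  c("a", "a_std", "a_subj.0", "a_subj.1",
                    "v", "v_std", "v_subj.0", "v_subj.1",
                    "t", "t_std", "t_subj.0", "t_subj.1",
                    "alpha", "alpha_std", "alpha_subj.0", "alpha_subj.1"))
})

test_that("condition splits create one group-level family per condition", {
  d <- simulate_rlddm_dataset(2, pst_schedule(6), seed = 2)
  m <- build_model(d, model_spec(depends_on = list(v = "split_by")))
  expect_true(all(c("v(AB)", "v(CD)", "v(EF)") %in% m$state_names))
  expect_false("v" %in% m$state_names)
  expect_true("v(AB)_subj.1" %in% m$state_names)
})

test_that("a regression replaces the parameter by intercept and slope families", {
  d <- simulate_rlddm_dataset(2, pst_schedule(6), seed = 2)
  d$neural <- rnorm(nrow(d))
  m <- build_model(validate_trials(as.data.frame(d)),
                   model_spec(regressions = "a ~ neural"))
  expect_true(all(c("a_Intercept", "a_neural", "a_Intercept_std",
                    "a_neural_std", "a_neural_subj.0") %in% m$state_names))
  expect_false("a" %in% m$state_names)
})

test_that("inconsistent specifications are rejected with configuration errors", {
  d <- simulate_rlddm_dataset(2, pst_schedule(6), seed = 2)
  d2 <- d; d2$neural <- rnorm(nrow(d2))
  expect_error(build_model(validate_trials(as.data.frame(d2)),
                           model_spec(depends_on = list(v = "split_by"),
                                      regressions = "v ~ neural")),
               class = "rlddm_config_error")
  expect_error(build_model(d, model_spec(regressions = "a ~ neural")),
               class = "rlddm_parse_error")  # covariate absent from data
  expect_error(build_model(d, model_spec(depends_on = list(v = "nope"))),
               class = "rlddm_config_error")
  expect_error(model_spec(include = "bogus"), class = "rlddm_config_error")
})

test_that("conflict series: functional form, standardization, degeneracy", {
  traj <- data.frame(q_upper = c(0.55, 0.8), q_lower = c(0.45, 0.4))
  raw <- conflict_series(traj, epsilon = 0.01, standardize = FALSE)
  expect_equal(raw, c(1 / 0.11, 1 / 0.41))
  std <- conflict_series(traj, epsilon = 0.01)
  expect_equal(mean(std), 0)
  expect_equal(sd(std), 1)
  # monotone decreasing in |q difference|
  expect_gt(raw[1], raw[2])
  neg <- conflict_series(traj, form = "negation", standardize = FALSE)
  expect_equal(neg, c(-0.1, -0.4))
  # equal values throughout: zero variance standardizes to all-zeros
  flat <- data.frame(q_upper = rep(0.5, 4), q_lower = rep(0.5, 4))
  expect_equal(conflict_series(flat), rep(0, 4))
  expect_error(conflict_series(traj, epsilon = 0), class = "rlddm_domain_error")
})

test_that("trial-parameter evaluation: links, nesting, linear propagation", {
  rs <- parse_formula("a ~ neural", "neural")
  dat <- data.frame(neural = c(-1, 0, 2))
  # zero slope returns the intercept unchanged
  expect_equal(evaluate_trial_parameter(rs, c(Intercept = 1.3, neural = 0), dat),
               rep(1.3, 3))
  expect_equal(evaluate_trial_parameter(rs, c(Intercept = 1, neural = 0.5), dat),
               c(0.5, 1, 2))
  # threshold floor for a non-positive linear predictor
  expect_equal(evaluate_trial_parameter(rs, c(Intercept = 0.1, neural = 1), dat)[1],
               1e-3)
  # drift regression with zero slope reduces to the plain scaled difference
  rv <- parse_formula("v ~ caudate", "caudate")
  qd <- c(0.2, -0.1, 0.4)
  expect_equal(evaluate_trial_parameter(rv, c(Intercept = 2, caudate = 0),
                                        data.frame(caudate = rnorm(3)),
                                        qdiff = qd),
               drift_rate(qd, 0, 2))
  # inverse-logit link for bounded targets
  rz <- parse_formula("z ~ neural", "neural")
  expect_equal(evaluate_trial_parameter(rz, c(Intercept = 0, neural = 1), dat),
               invlogit(dat$neural))
  # linearity of expectation over a standard-normal covariate
  set.seed(8)
  big <- data.frame(neural = rnorm(4000))
  vals <- evaluate_trial_parameter(rs, c(Intercept = 1, neural = 0.2), big)
  expect_equal(mean(vals), 1, tolerance = 0.02)
  expect_equal(sd(vals), 0.2, tolerance = 0.05)
})

test_that("a zero-coefficient regression model equals the base model likelihood", {
  d <- simulate_rlddm_dataset(2, pst_schedule(10), seed = 9)
  d$neural <- rnorm(nrow(d))
  tab <- validate_trials(as.data.frame(d))
  m0 <- build_model(tab)
  m1 <- build_model(tab, model_spec(regressions = "a ~ neural"))
  s0 <- initialize_state(m0, seed = 1)
  s1 <- initialize_state(m1, seed = 1)
  # align: intercept = base threshold, slope clamped to zero
  for (j in seq_along(m0$subjects)) {
    s1[sprintf("a_Intercept_subj.%s", m1$subjects[j])] <-
      s0[sprintf("a_subj.%s", m0$subjects[j])]
    s1[sprintf("a_neural_subj.%s", m1$subjects[j])] <- 0
    for (p in c("v", "t", "alpha")) {
      s1[sprintf("%s_subj.%s", p, m1$subjects[j])] <-
        s0[sprintf("%s_subj.%s", p, m0$subjects[j])]
    }
  }
  expect_equal(rlddm:::total_loglik(m1, s1), rlddm:::total_loglik(m0, s0))
})

test_that("subject-level transformed draws stay strictly inside (0, 1)", {
  d <- simulate_rlddm_dataset(3, pst_schedule(8), seed = 5)
  m <- build_model(d, model_spec(include = "z"))
  fit <- sample_posterior(m, n_samples = 60, burn = 20, seed = 3)
  s <- posterior_summary(fit)
  tr <- grep("_trans$", rownames(s), value = TRUE)
  expect_true(length(tr) > 0)
  expect_true(all(s[tr, "mean"] > 0 & s[tr, "mean"] < 1))
  expect_true(all(s[tr, "2.5q"] > 0 & s[tr, "97.5q"] < 1))
})

test_that("model specs round-trip through YAML", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("dual: true", "include: [z, sv]",
               "regressions: ['a ~ neural']"), f)
  spec <- read_model_spec(f)
  expect_true(spec$dual)
  expect_setequal(spec$include, c("z", "sv"))
  expect_identical(spec$regressions, "a ~ neural")
  writeLines("bogus_field: 1", f)
  expect_error(read_model_spec(f), class = "rlddm_config_error")
  unlink(f)
})
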