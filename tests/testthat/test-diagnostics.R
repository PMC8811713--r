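make_store <- function(..., chains = NULL, transformed = character(0)) {
  if (is.null(chains)) chains <- list(cbind(...))
  structure(list(draws = chains,
                 pars = setdiff(colnames(chains[[1]]), "deviance"),
                 transformed = transformed,
                 config = list(n_samples = nrow(chains[[1]]), burn = 0,
                               chains = length(chains), seed = 0)),
            class = "posterior_store")
}

test_that("posterior summary: constants, order statistics, transformed rows", {
  s <- posterior_summary(make_store(theta = rep(2.5, 50)))
  expect_equal(s["theta", "mean"], 2.5)
  expect_equal(s["theta", "std"], 0)
  expect_true(all(s["theta", 3:7] == 2.5))

  s2 <- posterior_summary(make_store(theta = 1:100))
  expect_equal(s2["theta", "mean"], 50.5)
  expect_equal(s2["theta", "50q"], 50.5)
  expect_equal(s2["theta", "2.5q"], as.numeric(quantile(1:100, 0.025)))
  expect_true(all(diff(as.numeric(s2["theta", 3:7])) >= 0))

  x <- rnorm(200)
  s3 <- posterior_summary(make_store(alpha = x, transformed = "alpha"))
  expect_equal(s3["alpha_trans", "mean"], mean(invlogit(x)))
  expect_equal(s3["alpha", "mean"], mean(x))
})

test_that("the worked inverse-logit transformation of a learning rate", {
  expect_equal(round(invlogit(-2.32), 2), 0.09)
})

test_that("summary CSV uses the exact documented header", {
  f <- tempfile(fileext = ".csv")
  write_summary(posterior_summary(make_store(a = rnorm(10))), f)
  expect_identical(readLines(f, n = 1), "mean,std,2.5q,25q,50q,75q,97.5q")
  unlink(f)
})

test_that("Gelman-Rubin separates mixed from unmixed chains", {
  set.seed(3)
  x <- matrix(rnorm(1e4), ncol = 1, dimnames = list(NULL, "p"))
  # identical chains: no between-chain variance
  r <- gelman_rubin(make_store(chains = list(x, x, x)))
  expect_lt(abs(r[["p"]] - 1), 1e-3)
  # iid chains from the same distribution
  ch <- lapply(1:3, function(i)
    matrix(rnorm(1e4), ncol = 1, dimnames = list(NULL, "p")))
  r2 <- gelman_rubin(make_store(chains = ch))
  expect_gte(r2[["p"]], 1 - 1e-3)
  expect_lt(r2[["p"]], 1.01)
  expect_true(attr(r2, "converged"))
  # diverged chains
  ch3 <- list(matrix(rnorm(1e3, 0), ncol = 1, dimnames = list(NULL, "p")),
              matrix(rnorm(1e3, 5), ncol = 1, dimnames = list(NULL, "p")))
  r3 <- gelman_rubin(make_store(chains = ch3))
  expect_gt(r3[["p"]], 1.1)
  expect_false(attr(r3, "converged"))
  expect_error(gelman_rubin(make_store(chains = ch3[1])),
               class = "rlddm_precondition_error")
})

test_that("Gelman-Rubin is invariant under a common affine transformation", {
  set.seed(5)
  ch <- lapply(1:3, function(i)
    matrix(rnorm(500, i * 0.05), ncol = 1, dimnames = list(NULL, "p")))
  r1 <- gelman_rubin(make_store(chains = ch))
  ch2 <- lapply(ch, function(m) m * 7 - 3)
  r2 <- gelman_rubin(make_store(chains = ch2))
  expect_equal(r1[["p"]], r2[["p"]], tolerance = 1e-12)
})

test_that("autocorrelation: lag zero, iid decay, AR(1) structure", {
  set.seed(7)
  x <- rnorm(1e4)
  ac <- chain_autocorrelation(x, max_lag = 10)
  expect_equal(ac[1], 1)
  expect_lt(abs(ac[2]), 0.05)  # ~ 2 / sqrt(n)
  # AR(1) with coefficient 0.9
  ar <- as.numeric(arima.sim(list(ar = 0.9), 2e4))
  ac_ar <- chain_autocorrelation(ar, max_lag = 3)
  expect_equal(ac_ar[2], 0.9, tolerance = 0.03)
  expect_error(chain_autocorrelation(rnorm(10), max_lag = 20),
               class = "rlddm_precondition_error")
})

test_that("DIC is the plug-in deviance for a degenerate posterior", {
  d <- simulate_rlddm_dataset(2, pst_schedule(8), seed = 43)
  m <- build_model(d)
  st <- initialize_state(m, seed = 1)
  dev <- -2 * rlddm:::total_loglik(m, st)
  chain <- matrix(rep(c(st, dev), each = 25), nrow = 25,
                  dimnames = list(NULL, c(names(st), "deviance")))
  res <- dic(make_store(chains = list(chain)), m)
  expect_equal(res$pd, 0, tolerance = 1e-9)
  expect_equal(res$dic, dev, tolerance = 1e-9)
})

test_that("an extra data-informed coefficient raises the effective parameter count", {
  set.seed(47)
  d <- simulate_rlddm_dataset(3, pst_schedule(20), seed = 47)
  d$noise <- rnorm(nrow(d))   # true effect zero
  tab <- validate_trials(as.data.frame(d))
  m0 <- build_model(tab)
  m1 <- build_model(tab, model_spec(regressions = "a ~ noise"))
  f0 <- sample_posterior(m0, n_samples = 300, burn = 120, seed = 3)
  f1 <- sample_posterior(m1, n_samples = 300, burn = 120, seed = 3)
  d0 <- dic(f0, m0)
  d1 <- dic(f1, m1)
  expect_gt(d1$pd, d0$pd)
  expect_gt(d0$pd, 0)
})

test_that("the highest-density interval is shortest and covers the mass", {
  set.seed(9)
  x <- rnorm(5000)
  h <- rlddm:::hdi(x, 0.9)
  expect_equal(mean(x >= h[1] & x <= h[2]), 0.9, tolerance = 0.01)
  expect_lt(h[2] - h[1],
            diff(quantile(x, c(0.025, 0.925))) + 0.05)
})
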