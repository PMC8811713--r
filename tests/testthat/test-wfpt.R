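test_that("wfpt density matches an independent fixed-term series", {
  set.seed(1)
  for (rep in 1:60) {
    a <- runif(1, 0.5, 3); v <- runif(1, -4, 4)
    t <- 0.3; z <- runif(1, 0.2, 0.8)
    rt <- t + runif(1, 0.01, 4)
    b <- sample(c("upper", "lower"), 1)
    expect_equal(wfpt_pdf(rt, b, a, v, t, z, tol = 1e-6),
                 wfpt_oracle(rt, b, a, v, t, z), tolerance = 1e-5)
  }
})

test_that("small- and large-time branches agree across the switch region", {
  # a dense rt sweep crosses the term-count switch point; the default
  # tolerance must hold against a high-precision evaluation throughout
  a <- 1.5; v <- 1; t <- 0.2; z <- 0.4
  rt <- seq(0.201, 4, by = 0.004)
  d_lo <- wfpt_pdf(rt, "upper", a, v, t, z, tol = 1e-4)
  d_hi <- wfpt_pdf(rt, "upper", a, v, t, z, tol = 1e-10)
  expect_lt(max(abs(d_lo - d_hi)), 1e-4)
})

test_that("density is zero at and before the non-decision time", {
  expect_equal(wfpt_pdf(c(0.1, 0.3), "upper", a = 1, v = 1, t = 0.3), c(0, 0))
})

test_that("the process is absorbed with probability one", {
  for (a in c(0.5, 1.5, 3)) {
    for (v in c(-4, -1, 0, 1, 4)) {
      for (z in c(0.2, 0.5, 0.8)) {
        tot <- wfpt_mass("upper", a, v, 0.3, z) +
          wfpt_mass("lower", a, v, 0.3, z)
        expect_equal(tot, 1, tolerance = 1e-4)
      }
    }
  }
})

test_that("driftless unbiased process splits mass evenly", {
  expect_equal(wfpt_mass("upper", 2, 0, 0.3, 0.5), 0.5, tolerance = 1e-5)
})

test_that("between-trial variability forms match numeric-integration oracles", {
  a <- 1.8; v <- 1; t <- 0.3; z <- 0.45; rt <- 1.1
  f0 <- function(rt, b, vv = v, tt = t, zz = z)
    wfpt_pdf(rt, b, a, vv, tt, zz, tol = 1e-8)
  # sv: Gaussian drift mixture
  num <- integrate(function(q) sapply(q, function(vi) f0(rt, "upper", vv = vi)) *
                     dnorm(q, v, 0.8), -12, 12)$value
  expect_equal(wfpt_pdf(rt, "upper", a, v, t, z, sv = 0.8, tol = 1e-8),
               num, tolerance = 1e-6)
  # st: uniform non-decision-time range
  num <- integrate(function(q) sapply(q, function(ti) f0(rt, "lower", tt = ti)),
                   t - 0.1, t + 0.1)$value / 0.2
  expect_equal(wfpt_pdf(rt, "lower", a, v, t, z, st = 0.2, tol = 1e-8),
               num, tolerance = 1e-6)
  # sz: uniform starting-point range
  num <- integrate(function(q) sapply(q, function(zi) f0(rt, "upper", zz = zi)),
                   z - 0.1, z + 0.1)$value / 0.2
  expect_equal(wfpt_pdf(rt, "upper", a, v, t, z, sz = 0.2, tol = 1e-8),
               num, tolerance = 1e-6)
})

test_that("parameter domain is enforced", {
  expect_error(wfpt_pdf(1, "upper", a = -1, v = 0, t = 0.3),
               class = "rlddm_domain_error")
  expect_error(wfpt_pdf(1, "upper", a = 1, v = 0, t = -0.1),
               class = "rlddm_domain_error")
  expect_error(wfpt_pdf(1, "upper", a = 1, v = 0, t = 0.3, z = 1.2),
               class = "rlddm_domain_error")
  expect_error(wfpt_pdf(1, "upper", a = 1, v = 0, t = 0.3, z = 0.9, sz = 0.3),
               class = "rlddm_domain_error")
  expect_error(wfpt_pdf(1, "upper", a = 1, v = 0, t = 0.1, st = 0.3),
               class = "rlddm_domain_error")
  expect_error(wfpt_pdf(1, "sideways", a = 1, v = 0, t = 0.1),
               class = "rlddm_domain_error")
})

test_that("closed-form absorption probability: limits and integral agreement", {
  expect_equal(choice_prob_upper(2, 0, 0.3), 0.3)  # driftless: equals z
  expect_equal(choice_prob_upper(1.5, 1.2, 0.4),
               wfpt_mass("upper", 1.5, 1.2, 0.3, 0.4), tolerance = 1e-5)
})

test_that("choice probability at z = 0.5 is a softmax with beta = a * v", {
  for (a in seq(0.5, 3, by = 0.5)) {
    for (v in seq(-4, 4, by = 0.8)) {
      expect_equal(choice_prob_upper(a, v, 0.5), plogis(a * v),
                   tolerance = 1e-14)
    }
  }
})

test_that("rlddm log-likelihood reduces to known cases", {
  tab <- tiny_table()
  # single trial equals the log density of that trial
  one <- tab[1, , drop = FALSE]
  ll1 <- rlddm_loglik(validate_trials(as.data.frame(one)),
                      a = 1.5, v_scale = 2, t = 0.2, alpha = 0.3)
  expect_equal(ll1, log(wfpt_pdf(one$rt, "upper", 1.5, 0, 0.2, 0.5)))
  # alpha = 0 and equal q_init: drift stays 0, static DDM
  ll <- rlddm_loglik(tab, a = 1.5, v_scale = 2, t = 0.2, alpha = 0)
  static <- sum(log(wfpt_pdf(tab$rt, tab$response, 1.5, 0, 0.2, 0.5)))
  expect_equal(ll, static)
})

test_that("rt at or below the non-decision time flags a non-finite likelihood", {
  tab <- tiny_table()
  ll <- rlddm_loglik(tab, a = 1.5, v_scale = 2, t = 0.65, alpha = 0.1)
  expect_identical(as.numeric(ll), -Inf)
  expect_true(isTRUE(attr(ll, "nonfinite")))
})

test_that("likelihood concentrates at the generating parameters", {
  set.seed(21)
  wins <- 0
  n_rep <- 12
  for (r in 1:n_rep) {
    d <- simulate_rlddm_dataset(1, pst_schedule(70),
                                group = list(a = 1.8, v = 2.5, t = 0.3,
                                             alpha = 0.25),
                                sds = list(a = 1e-6, v = 1e-6, t = 1e-6,
                                           alpha = 1e-6))
    ll_true <- rlddm_loglik(d, 1.8, 2.5, 0.3, 0.25)
    ll_pert <- rlddm_loglik(d, 1.8 * 1.5, 2.5 * 0.5, 0.3 * 0.5, 0.25 * 1.5)
    if (ll_true > ll_pert) wins <- wins + 1
  }
  expect_gte(wins, n_rep - 1)
})

test_that("softmax likelihood: flat cases and marginal-choice equivalence", {
  tab <- tiny_table()
  expect_equal(rl_softmax_loglik(tab, alpha = 0.3, beta = 0),
               nrow(tab) * log(0.5))
  expect_equal(rl_softmax_loglik(tab, alpha = 0, beta = 3),
               nrow(tab) * log(0.5))  # Q never separates
  # integrating the wfpt over RT per trial reproduces the softmax model
  # with beta = a * v_scale (z = 0.5, no between-trial variability)
  a <- 1.4; vs <- 2.2; alpha <- 0.35
  ll_sm <- rl_softmax_loglik(tab, alpha = alpha, beta = a * vs)
  ll_int <- 0
  for (cnd in unique(tab$split_by)) {
    blk <- tab[tab$split_by == cnd, ]
    traj <- compute_q_trajectory(blk, alpha)
    for (i in seq_len(nrow(blk))) {
      vi <- (traj$q_upper[i] - traj$q_lower[i]) * vs
      p_up <- integrate(function(x) wfpt_pdf(x, "upper", a, vi, 0.3, 0.5,
                                             tol = 1e-8),
                        0.3, Inf, rel.tol = 1e-9)$value
      ll_int <- ll_int + log(if (blk$response[i] == 1) p_up else 1 - p_up)
    }
  }
  expect_equal(ll_int, ll_sm, tolerance = 1e-5)
})
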