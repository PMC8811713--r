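# Independent oracles used across test files. These deliberately do not
# share code with the package implementation.

# Wiener first-passage density via direct series summation with a fixed,
# large number of terms: the small-time sum for small normalized times and
# the large-time sum otherwise (independent of the package's adaptive
# term-count branching).
wfpt_oracle <- function(rt, boundary, a, v, t, z) {
  u <- rt - t
  if (u <= 0) return(0)
  w <- if (boundary == "upper" || boundary == 1) 1 - z else z
  vv <- if (boundary == "upper" || boundary == 1) -v else v
  tt <- u / a^2
  if (tt < 0.5) {
    k <- -200:200
    p <- sum((w + 2 * k) * exp(-(w + 2 * k)^2 / (2 * tt))) /
      sqrt(2 * pi * tt^3)
  } else {
    k <- 1:2000
    p <- pi * sum(k * exp(-k^2 * pi^2 * tt / 2) * sin(k * pi * w))
  }
  p * exp(-vv * a * w - vv^2 * u / 2) / a^2
}

# One-sample Kolmogorov-Smirnov statistic of simulated signed RTs
# (upper-boundary positive, lower-boundary negative) against the signed CDF
# implied by a density function pdf(rt, boundary).
signed_ks_stat <- function(response, rt, pdf_fun, t, grid_n = 6000) {
  grid <- seq(t + 1e-4, max(rt) + 1, length.out = grid_n)
  dg <- diff(grid)[1]
  Fu <- cumsum(pdf_fun(grid, "upper")) * dg
  Fl <- cumsum(pdf_fun(grid, "lower")) * dg
  Pl <- Fl[length(Fl)]
  s <- sort(ifelse(response == 1, rt, -rt))
  Fs <- ifelse(s < 0,
               Pl - stats::approx(grid, Fl, -s, rule = 2)$y,
               Pl + stats::approx(grid, Fu, pmax(s, grid[1]), rule = 2)$y)
  i <- seq_along(s)
  max(abs(i / length(s) - Fs), abs((i - 1) / length(s) - Fs))
}

# Integral of the wfpt density over all RTs for one boundary.
wfpt_mass <- function(boundary, a, v, t, z, tol = 1e-6) {
  stats::integrate(function(x) wfpt_pdf(x, boundary, a, v, t, z, tol = tol),
                   t, Inf, rel.tol = 1e-8)$value
}

# A tiny deterministic trial table built in code.
tiny_table <- function() {
  validate_trials(data.frame(
    rt = c(0.8, 1.1, 0.7, 0.9, 1.4, 0.6),
    response = c(1, 1, 0, 1, 0, 1),
    split_by = rep(c("AB", "CD"), each = 3),
    subj_idx = 0L,
    feedback = c(1, 0, 1, 1, 0, 1),
    q_init = 0.5))
}

# Effective-sample-size-adjusted Monte-Carlo standard error of a chain mean.
mcse <- function(x) {
  n <- length(x)
  rho <- as.numeric(stats::acf(x, lag.max = min(n - 1, 200),
                               plot = FALSE)$acf)[-1]
  neg <- which(rho <= 0)
  if (length(neg) > 0) rho <- rho[seq_len(neg[1] - 1)]
  ess <- max(4, n / (1 + 2 * sum(rho)))
  stats::sd(x) / sqrt(ess)
}
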