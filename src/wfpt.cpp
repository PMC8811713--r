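// Wiener first-passage-time density (Navarro & Fuss 2009 series approximation)
// and the composed RLDDM / softmax-RL block log-likelihoods.
//
// Scaling convention: within-trial diffusion coefficient fixed at 1.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 11-node Gauss-Legendre rule on [-1, 1], used for the uniform
// between-trial perturbations of non-decision time and starting point.
static const int GL_N = 11;
static const double GL_X[GL_N] = {
  -9.7822865814605697e-01, -8.8706259976809532e-01, -7.3015200557404936e-01,
  -5.1909612920681181e-01, -2.6954315595234496e-01, 0.0,
   2.6954315595234496e-01,  5.1909612920681181e-01,  7.3015200557404936e-01,
   8.8706259976809532e-01,  9.7822865814605697e-01 };
static const double GL_W[GL_N] = {
  5.5668567116173927e-02, 1.2558036946490433e-01, 1.8629021092773429e-01,
  2.3319376459199057e-01, 2.6280454451024654e-01, 2.7292508677790051e-01,
  2.6280454451024654e-01, 2.3319376459199057e-01, 1.8629021092773429e-01,
  1.2558036946490433e-01, 5.5668567116173927e-02 };

// Density of the normalized (a = 1, v = 0) process hitting the lower bound at
// normalized time tt, relative start w.  Branch between the small-time and
// large-time series by the Navarro-Fuss term-count criterion at absolute
// error `err`.
static double ftt_01w(double tt, double w, double err) {
  double kl, ks;
  if (M_PI * tt * err < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * err) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * err < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * std::sqrt(2.0 * M_PI * tt) * err));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }
  double p = 0.0;
  if (ks < kl) {  // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = -(int)std::floor((K - 1) / 2.0);
    int hi = (int)std::ceil((K - 1) / 2.0);
    for (int k = lo; k <= hi; ++k) {
      double wk = w + 2.0 * k;
      p += wk * std::exp(-wk * wk / (2.0 * tt));
    }
    p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {        // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) *
           std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  return p;
}

// Lower-boundary first-passage density at decision time u (= rt - t),
// drift v, threshold a, relative start w; sv is the between-trial drift SD
// (analytic Gaussian-mixture form when sv > 0).
static double wfpt_lower(double u, double v, double a, double w,
                         double sv, double err) {
  if (u <= 0.0) return 0.0;
  double tt = u / (a * a);
  double p = ftt_01w(tt, w, err);
  if (p < 0.0) p = 0.0;  // series truncation can dip below zero in deep tails
  double mult;
  if (sv > 0.0) {
    double sv2 = sv * sv;
    mult = std::exp((a * w * sv * a * w * sv - 2.0 * a * v * w - v * v * u) /
                    (2.0 * (sv2 * u + 1.0))) /
           std::sqrt(sv2 * u + 1.0);
  } else {
    mult = std::exp(-v * a * w - v * v * u / 2.0);
  }
  return p * mult / (a * a);
}

// Full density for one observation; upper = 1 means the response hit the
// upper boundary.  st and sz are the ranges of uniform between-trial
// perturbations on t and z, integrated by Gauss-Legendre quadrature.
static double wfpt_pdf_one(double rt, int upper, double a, double v,
                           double t, double z, double sv, double st,
                           double sz, double err) {
  double w = upper ? 1.0 - z : z;
  double vv = upper ? -v : v;
  if (st <= 0.0 && sz <= 0.0) {
    return wfpt_lower(rt - t, vv, a, w, sv, err);
  }
  double acc = 0.0;
  if (st > 0.0 && sz > 0.0) {
    for (int i = 0; i < GL_N; ++i) {
      double ti = t + 0.5 * st * GL_X[i];
      double inner = 0.0;
      for (int j = 0; j < GL_N; ++j) {
        double wj = w + 0.5 * sz * GL_X[j];
        inner += GL_W[j] * wfpt_lower(rt - ti, vv, a, wj, sv, err);
      }
      acc += GL_W[i] * inner / 2.0;
    }
    acc /= 2.0;
  } else if (st > 0.0) {
    for (int i = 0; i < GL_N; ++i) {
      double ti = t + 0.5 * st * GL_X[i];
      acc += GL_W[i] * wfpt_lower(rt - ti, vv, a, w, sv, err);
    }
    acc /= 2.0;
  } else {
    for (int j = 0; j < GL_N; ++j) {
      double wj = w + 0.5 * sz * GL_X[j];
      acc += GL_W[j] * wfpt_lower(rt - t, vv, a, wj, sv, err);
    }
    acc /= 2.0;
  }
  return acc;
}

// [[Rcpp::export]]
NumericVector wfpt_pdf_cpp(NumericVector rt, IntegerVector upper,
                           NumericVector a, NumericVector v,
                           NumericVector t, NumericVector z,
                           double sv, double st, double sz, double err) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double ai = a[a.size() == 1 ? 0 : i];
    double vi = v[v.size() == 1 ? 0 : i];
    double ti = t[t.size() == 1 ? 0 : i];
    double zi = z[z.size() == 1 ? 0 : i];
    out[i] = wfpt_pdf_one(rt[i], upper[upper.size() == 1 ? 0 : i],
                          ai, vi, ti, zi, sv, st, sz, err);
  }
  return out;
}

static inline double pick(const NumericVector& x, int i) {
  return x[x.size() == 1 ? 0 : i];
}

// RLDDM log-likelihood for an ordered set of trials (possibly several
// subject-by-condition blocks, identified by contiguous `block` ids).
// Q values evolve by the delta rule within each block; the trial drift is
// (q_upper - q_lower) * vscale[i].  a, vscale, t, z may be per-trial.
// Returns -Inf when any trial has rt <= t, a below the positivity floor,
// or z outside (0, 1).
// [[Rcpp::export]]
double rlddm_block_loglik_cpp(NumericVector rt, IntegerVector response,
                              NumericVector feedback, IntegerVector block,
                              NumericVector q_init,
                              NumericVector a, NumericVector vscale,
                              NumericVector t, NumericVector z,
                              double alpha, double alpha_neg, bool dual,
                              double sv, double st, double sz,
                              double err, double a_floor) {
  int n = rt.size();
  double ll = 0.0;
  int cur_block = NA_INTEGER;
  double qu = 0.0, ql = 0.0;
  for (int i = 0; i < n; ++i) {
    if (block[i] != cur_block) {
      cur_block = block[i];
      qu = q_init[i];
      ql = q_init[i];
    }
    double ai = pick(a, i), ti = pick(t, i), zi = pick(z, i);
    if (ai <= a_floor || zi <= 0.0 || zi >= 1.0 || ti < 0.0)
      return R_NegInf;
    if (rt[i] <= ti) return R_NegInf;
    double vi = (qu - ql) * pick(vscale, i);
    double dens = wfpt_pdf_one(rt[i], response[i], ai, vi, ti, zi,
                               sv, st, sz, err);
    if (dens <= 0.0 || !std::isfinite(dens)) return R_NegInf;
    ll += std::log(dens);
    // delta-rule update of the chosen option only
    double q_ch = response[i] == 1 ? qu : ql;
    double rpe = feedback[i] - q_ch;
    double lr = (dual && rpe < 0.0) ? alpha_neg : alpha;
    q_ch += lr * rpe;
    if (response[i] == 1) qu = q_ch; else ql = q_ch;
  }
  return ll;
}

// Softmax-RL log-likelihood (choice only, no RTs).  beta may be per-trial.
// [[Rcpp::export]]
double rl_softmax_block_loglik_cpp(IntegerVector response,
                                   NumericVector feedback,
                                   IntegerVector block, NumericVector q_init,
                                   NumericVector beta,
                                   double alpha, double alpha_neg,
                                   bool dual) {
  int n = response.size();
  double ll = 0.0;
  int cur_block = NA_INTEGER;
  double qu = 0.0, ql = 0.0;
  for (int i = 0; i < n; ++i) {
    if (block[i] != cur_block) {
      cur_block = block[i];
      qu = q_init[i];
      ql = q_init[i];
    }
    double b = pick(beta, i);
    // overflow-safe log softmax
    double xu = b * qu, xl = b * ql;
    double m = std::max(xu, xl);
    double lse = m + std::log(std::exp(xu - m) + std::exp(xl - m));
    ll += (response[i] == 1 ? xu : xl) - lse;
    double q_ch = response[i] == 1 ? qu : ql;
    double rpe = feedback[i] - q_ch;
    double lr = (dual && rpe < 0.0) ? alpha_neg : alpha;
    q_ch += lr * rpe;
    if (response[i] == 1) qu = q_ch; else ql = q_ch;
  }
  return ll;
}

// Q-value trajectory for one ordered block: returns matrix with columns
// q_upper, q_lower, rpe (values *before* the trial's update, i.e. the
// expectations the decision was based on).
// [[Rcpp::export]]
NumericMatrix q_trajectory_cpp(IntegerVector response, NumericVector feedback,
                               double q_init, double alpha, double alpha_neg,
                               bool dual) {
  int n = response.size();
  NumericMatrix out(n, 3);
  double qu = q_init, ql = q_init;
  for (int i = 0; i < n; ++i) {
    out(i, 0) = qu;
    out(i, 1) = ql;
    double q_ch = response[i] == 1 ? qu : ql;
    double rpe = feedback[i] - q_ch;
    out(i, 2) = rpe;
    double lr = (dual && rpe < 0.0) ? alpha_neg : alpha;
    q_ch += lr * rpe;
    if (response[i] == 1) qu = q_ch; else ql = q_ch;
  }
  return out;
}
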