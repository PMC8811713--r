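// Forward simulation of DDM first-passage trials and full RLDDM agents.
//
// Euler-Maruyama discretization (default dt = 1e-4) with a Brownian-bridge
// crossing check at every step, which removes the leading O(sqrt(dt))
// first-passage bias of the bare scheme.  Uses R's RNG so results are
// reproducible under set.seed().
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One first-passage outcome for fixed (a, v, t, z); between-trial
// variability is applied by the caller.  Returns (boundary, rt) with
// boundary 1 = upper.  Trials not absorbed within max_t are redrawn.
static void one_trial(double a, double v, double t, double z,
                      double dt, double max_t, int& boundary, double& rt) {
  double sqdt = std::sqrt(dt);
  for (;;) {  // redraw loop for the (rare) > max_t case
    double x = z * a;
    double tm = 0.0;
    while (tm < max_t) {
      double xn = x + v * dt + sqdt * norm_rand();
      tm += dt;
      if (xn >= a) { boundary = 1; rt = t + tm; return; }
      if (xn <= 0.0) { boundary = 0; rt = t + tm; return; }
      // Brownian bridge: probability the path crossed within the step.
      // Skipped when both endpoints are far from a boundary (crossing
      // probability < exp(-24), far below any attainable resolution).
      double du = (a - x) * (a - xn);
      if (du < 12.0 * dt &&
          unif_rand() < std::exp(-2.0 * du / dt)) {
        boundary = 1; rt = t + tm; return;
      }
      double dl = x * xn;
      if (dl < 12.0 * dt &&
          unif_rand() < std::exp(-2.0 * dl / dt)) {
        boundary = 0; rt = t + tm; return;
      }
      x = xn;
    }
  }
}

static inline double trunc_unif(double c, double half) {
  return half > 0.0 ? c + unif_rand() * 2.0 * half - half : c;
}

// [[Rcpp::export]]
DataFrame sample_ddm_trials_cpp(int n, double a, NumericVector v, double t,
                                double z, double sv, double st, double sz,
                                double dt, double max_t) {
  IntegerVector boundary(n);
  NumericVector rt(n);
  for (int i = 0; i < n; ++i) {
    double vi = v[v.size() == 1 ? 0 : i];
    if (sv > 0.0) vi += norm_rand() * sv;
    double ti = trunc_unif(t, st / 2.0);
    double zi = trunc_unif(z, sz / 2.0);
    int b; double r;
    one_trial(a, vi, ti, zi, dt, max_t, b, r);
    boundary[i] = b;
    rt[i] = r;
  }
  return DataFrame::create(_["response"] = boundary, _["rt"] = rt);
}

// One RLDDM agent on one condition block: simulate choice/RT from the
// evolving Q values, draw Bernoulli feedback for the chosen option, update
// the chosen option's Q by the delta rule.  a may be per-trial (regression
// designs).  Returns response, rt, feedback plus the pre-decision Q values.
// [[Rcpp::export]]
DataFrame sim_rlddm_block_cpp(int n_trials, NumericVector a, double vscale,
                              double t, double z, double alpha,
                              double alpha_neg, bool dual,
                              double q_init, double p_upper, double p_lower,
                              double sv, double st, double sz,
                              double dt, double max_t) {
  IntegerVector response(n_trials);
  NumericVector rt(n_trials), feedback(n_trials);
  NumericVector qu_out(n_trials), ql_out(n_trials);
  double qu = q_init, ql = q_init;
  for (int i = 0; i < n_trials; ++i) {
    qu_out[i] = qu; ql_out[i] = ql;
    double vi = (qu - ql) * vscale;
    if (sv > 0.0) vi += norm_rand() * sv;
    double ti = trunc_unif(t, st / 2.0);
    double zi = trunc_unif(z, sz / 2.0);
    double ai = a[a.size() == 1 ? 0 : i];
    int b; double r;
    one_trial(ai, vi, ti, zi, dt, max_t, b, r);
    response[i] = b;
    rt[i] = r;
    double p_rew = b == 1 ? p_upper : p_lower;
    double f = unif_rand() < p_rew ? 1.0 : 0.0;
    feedback[i] = f;
    double q_ch = b == 1 ? qu : ql;
    double rpe = f - q_ch;
    double lr = (dual && rpe < 0.0) ? alpha_neg : alpha;
    q_ch += lr * rpe;
    if (b == 1) qu = q_ch; else ql = q_ch;
  }
  return DataFrame::create(_["response"] = response, _["rt"] = rt,
                           _["feedback"] = feedback,
                           _["q_upper"] = qu_out, _["q_lower"] = ql_out);
}
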