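---
title: "Methods: the reinforcement learning drift diffusion model in rlddm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the reinforcement learning drift diffusion model in rlddm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`rlddm` estimates learning and decision parameters jointly for
two-alternative instrumental learning tasks in which a participant chooses
repeatedly between a better and a worse option and receives probabilistic
feedback. Two ingredients are combined.

**Value learning.** Each option's expected value follows the delta rule:
on every trial the chosen option's expectation moves toward the received
reward in proportion to the reward prediction error,
$Q \leftarrow Q + \alpha\,(r - Q)$, with learning rate
$\alpha \in (0,1)$. The unchosen option's value is carried forward
unchanged, and values are tracked separately per task condition
(`split_by`), since only the displayed pair should be updated. With
`dual = TRUE` two learning rates are estimated, one for positive and one
for negative prediction errors; a prediction error of exactly zero takes
the positive branch (a deterministic tie-break for an event of measure
zero under continuous rewards — and one with no observable consequence,
since a zero error updates nothing).

**Choice and latency.** Instead of a softmax, choices are modelled as a
Wiener diffusion between two absorbing boundaries: evidence accumulates
with drift $v_i = (Q_{\mathrm{upper},i} - Q_{\mathrm{lower},i})\,v$ — the
value difference scaled by a free parameter $v$ that plays the
exploration/exploitation role of the softmax inverse temperature — from a
relative starting point $z$ toward threshold $a$, plus a non-decision time
$t$. The likelihood of a (choice, RT) pair is the Wiener first-passage-time
(wfpt) density. The package fixes the within-trial diffusion coefficient at
1, the scaling convention of the wider hierarchical-DDM ecosystem; all
parameter values are expressed in that convention. A DDM that ignores RT
reduces to a softmax with inverse temperature $a \cdot v$ (for $z = 0.5$),
and a softmax-only model (`choice_rule = "softmax"`) is available for data
without response times.

## Likelihood evaluation

The wfpt density is evaluated by the standard series approximation with two
expansions — one accurate at small normalized times, one at large — and the
branch is chosen per evaluation by the expansions' term-count criterion at
an absolute error bound (`tol`, default $10^{-4}$). The "full" DDM
extensions are supported at the single-trial level: between-trial drift
variability `sv` uses the closed-form Gaussian-mixture density, and uniform
between-trial perturbations of `t` (range `st`) and `z` (range `sz`) are
integrated with 11-node Gauss–Legendre quadrature, which is exact to well
below `tol` for these smooth integrands. An RT at or below the
non-decision time has density zero and the corresponding log-likelihood is
flagged `-Inf`; the sampler simply rejects such states. No outlier-mixture
component is included — extreme observations are the user's preprocessing
concern. Between-trial variability parameters perturb the single-trial DDM
only; they do not interact with the learning process.

## Hierarchical structure and priors

Every estimated parameter family has a group mean, a group SD, and one
value per subject. Defaults (see `default_priors()`):

| family | group mean | group SD | subjects | link |
|---|---|---|---|---|
| threshold $a$ | Gamma(mean 1.5, rate 0.75) | HalfNormal(0.1) | Gamma(mean, SD) | identity |
| drift scaling $v$ | Normal(2, 3) | HalfNormal(2) | Normal | identity |
| non-decision $t$ (s) | Gamma(mean 0.4, rate 0.2) | HalfNormal(1) | Normal | identity (support from likelihood) |
| starting point $z$ | Normal(0.5, 0.5) | HalfNormal(0.5) | Normal | inverse logit |
| learning rate $\alpha$ | Normal(0, 3) | HalfNormal(2) | Normal | inverse logit |
| `sv`, `st`, `sz` | HalfNormal(2), HalfNormal(0.3), Beta(1, 3) | — | group-only | — |

Gamma distributions are parameterized by mean and rate at the group level
and by mean and SD at the subject level. The DDM priors are informative
(from published meta-analytic fits); the learning-rate prior is a wide
normal on the unconstrained scale, centred at 0.5 after the inverse-logit
transform. Learning rates and starting points are sampled unconstrained and
reported on both scales (`_trans` rows in `posterior_summary()`). The
between-trial variabilities are group-only because they are poorly
identified per subject. Subject-level non-decision times get a plain normal
prior whose negative tail is cut off by the likelihood's support — an
implicit truncation we prefer over a renormalized truncated normal because
it keeps every conditional density a simple product.

Condition splits (`depends_on`) create one family per condition level.
Trial-wise regressions (`a ~ neural`) replace a family by one family per
coefficient: intercepts inherit the target parameter's group prior, slopes
get Normal(0, 2) group priors, and both use the target's group-SD prior for
their subject-level spread. Identity-link regressions can drive a threshold
non-positive; such states are assigned `-Inf` likelihood (with a $10^{-3}$
floor guarding the arithmetic) rather than crashing the sampler. The
learning rate must be part of any regression model, since the Q-value
trajectory that drives the drift depends on it.

**Conflict.** The latent regressor `conflict` is high when options have
similar learned values. The published description — the "inverse" of the
difference in expected rewards — is ambiguous between a reciprocal and a
negation, so both are implemented: the default is
$1 / (|Q_\Delta| + \epsilon)$ with $\epsilon = 0.01$
(`conflict_form = "reciprocal"`), with $-|Q_\Delta|$ available as
`"negation"`. Either series is standardized within subject before entering
the design matrix; a zero-variance series standardizes to all-zeros so that
degenerate early-learning blocks remain estimable. Because conflict depends
on the learning rate, it is recomputed inside the likelihood whenever the
subject's $\alpha$ changes.

Interaction grammars follow R formulas: `x*y` expands to main effects plus
the interaction (all lower-order terms included), `x:y` is the interaction
alone, and `0 +` drops the intercept.

## Sampling

Posteriors are approximated by Markov chain Monte Carlo with univariate
slice sampling (stepping-out and shrinkage) applied to each free node in
turn: initial width 1 on the sampling scale, at most 10 interval
expansions, no thinning, no adaptation — which keeps runs exactly
reproducible given a seed. Group-node conditionals involve only the
subject-level densities of their family, so they are cheap; subject-node
conditionals re-evaluate that subject's trial likelihood, implemented in
C++. The Q-trajectory recursion is recomputed inside each likelihood call:
it is linear in the trial count and costs a negligible fraction of the wfpt
series evaluation, so caching it per parameter subset would add bookkeeping
without measurable speedup. Initialization draws group nodes from their
priors and subjects from their groups, retrying (bounded) until the joint
density is finite; non-decision times are resampled below each subject's
fastest RT, and regression slopes start near zero (their prior mean), since
a prior-scale slope almost surely drives some trial's threshold negative.
The tutorial-style defaults are 1500 draws with 500 burn-in and one chain;
convergence checks use three.

## Diagnostics and model comparison

`posterior_summary()` pools chains and reports mean, SD and the
2.5/25/50/75/97.5 percentiles (linear-interpolation quantiles, R type 7,
fixed for reproducibility). `gelman_rubin()` implements the classic
potential-scale-reduction factor (no rank normalization), with the
customary 1.1 bound surfaced as a `converged` flag, not an error; note the
estimator equals $\sqrt{(n-1)/n}$, marginally below 1, for perfectly
identical chains. `dic()` reports deviance-based fit,
$\mathrm{DIC} = \bar D + p_D$ with $p_D = \bar D - D(\bar\theta)$, where
the posterior mean $\bar\theta$ of transformed parameters is taken on the
unconstrained scale — the scale the sampler explores, so the plug-in point
is the centroid of the actual chain. No WAIC/LOO is provided.

## Posterior predictive checks

`posterior_predict()` draws joint parameter vectors from the store,
simulates complete datasets on the task schedule, and aggregates three
displays: choice-proportion curves in 4-trial bins per condition with a 90%
highest-density band of the replicate means; RT densities with
lower-boundary RTs negated ($0 - \mathrm{RT}$) to separate the two
response streams; and quantile-probability data, with RT quantiles fixed at
10/30/50/70/90% (the field's convention) within low/medium/high difficulty
terciles of $|Q_\Delta|$. Observed data enter these outputs only as
overlays; the difficulty terciles for the observed side use Q trajectories
reconstructed under posterior-mean learning rates, and for the simulated
side the simulated trajectories themselves.

## The simulator as study-condition generator

The generator's defaults are the study conditions used throughout the
tests: the probabilistic selection task with reward probabilities 0.8/0.2,
0.7/0.3 and 0.6/0.4, `q_init = 0.5` (the unbiased value for 0/1 rewards),
60 trials per condition, and group parameters a = 2.0, v = 2.25, t = 0.4 s,
alpha = 0.3 with subject SDs 0.1, 0.25, 0.02 s and 0.1 — the centre of the
recovery grid (`recovery_design()` crosses a ∈ {1.5, 2, 2.5},
t ∈ {0.3, 0.4, 0.5}, alpha ∈ {0.15, 0.3, 0.45}, v ∈ {1.5, 2.25, 3}; 81
cells, 40 subjects by default). The regression demonstration uses 30
subjects, a Normal(0, 1) trial-wise covariate, and a baseline threshold of
1 and coefficient of 0.2 that are both *fixed* across subjects: the
demonstration's published posterior spread of the recovered intercept
(~0.006) is an order of magnitude below what any appreciable
between-subject baseline spread would force on the group mean, so a fixed
baseline is the faithful reading (`baseline_sd` re-enables heterogeneity).

Two generator choices deserve note. First, subject learning rates are drawn
on the unconstrained scale around logit of the group mean, with the
SD stated on the probability scale converted by the delta method
(`alpha_scale = "unconstrained"`); drawing directly on the probability
scale is available (`"probability"`) because the original recovery study
does not state which scale its SD of 0.1 applied to. Second, first-passage
outcomes are simulated by Euler–Maruyama with step `dt = 1e-4` and a
Brownian-bridge crossing check at every step. The bridge check matters: the
bare scheme's first-passage bias is of order $\sqrt{dt}$, which at this
step size is comparable to the Kolmogorov–Smirnov tolerance the test suite
holds the generator to ($\approx 5\times 10^{-3}$ at $10^5$ samples), while
the corrected scheme passes with a wide margin. Walks not absorbed within
20 s of decision time are redrawn; for the parameter ranges used here the
unabsorbed-by-20-s mass is below $10^{-6}$ (the large-time eigenvalue
$\pi^2/(2a^2)$ times 20 s dominates even at the largest thresholds in the
recovery grid), so the truncation is negligible — a limitation only for
far larger thresholds or strongly biased starting points. Predictive
simulation in `posterior_predict()` uses a coarser default step
(`dt = 1e-3`) since predictive uncertainty dwarfs discretization error
there.

## Problem sizes and numerical choices in the test suite

The package's own validation runs at desk scale: regression recovery at 30
subjects × 180 trials with 1000 draws; group-parameter recovery and the
three-chain convergence check at 10–20 subjects × 90–180 trials with
800–1500 draws; density normalization on a grid covering a ∈ [0.5, 3],
|v| ≤ 4, z ∈ [0.2, 0.8]; generator-vs-density agreement at $10^5$ samples
for five seeded parameter sets; prior fidelity at $10^5$ draws. These sizes
were chosen as the smallest at which the published recovery behaviour is
clearly expressed.

Other numerical conventions: softmax and inverse-logit computations are
max-shifted/overflow-safe; `choice_prob_upper()` uses `expm1` with the
driftless limit handled exactly as $z$; the wfpt series value is clamped at
zero where deep-tail truncation would produce a tiny negative density;
quantiles everywhere are type 7.

## Limitations

Two response options only, and at most two concurrently tracked values per
condition. No eligibility traces, forgetting, uncertainty-scaled learning
rates, or sigmoid drift transforms. No gradient-based samplers: the series
approximation's branch switching makes reliable gradients a separate
engineering project, and univariate slice sampling needs no tuning. The
regression language covers linear terms and interactions of data columns
plus the single latent `conflict` series; general latent-state regression
is out of scope. `posterior_predict()` covers base and condition-split
models, not regression models (whose covariates have no generative model on
new trials). Passing the synthetic-data checks shows the pipeline is
self-consistent at realistic parameter values; real datasets bring
contaminant RTs, non-stationary learning and unmodelled slow drifts that
the generator deliberately does not emulate.
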