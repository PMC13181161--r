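---
title: "Joint models with a within-individual variability association: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint models with a within-individual variability association: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

In chronic-disease monitoring, the visit-to-visit *within-individual
variability* (WIV) of a biomarker — how much it fluctuates around its own
trend — can itself carry prognostic information. Two-stage approaches that
compute a per-subject standard deviation and feed it into a survival model
are biased: the variability summary is estimated with error (regression
dilution attenuates its hazard ratio towards the null), it ignores time
trends in the variability, and restricting to subjects with enough visits
introduces immortal-time bias.

`jmwiv` fits the joint model that addresses these problems in one stage: a
*mixed-effects location-scale model* (MELSM) for several longitudinal
biomarkers, linked to a proportional-hazards model for a right-censored
(possibly left-truncated) event time through association terms that involve
the biomarkers' variability as well as their means.

## The model

**Longitudinal submodel.** For subject $i$, visit time $t_{ij}$ and
biomarker $k = 1, \dots, K$:
$$
y_{ijk} \sim N\!\big(\eta_{i\mu k}(t_{ij}),\; \sigma_{ijk}^2\big), \qquad
\log \sigma_{ijk} = \eta_{i\sigma k}(t_{ij}),
$$
with structural additive predictors
$\eta_{i\psi k}(t) = X_{i\psi k}(t)\beta_{\psi k} + Z_{i\psi k}(t) b_{i\psi k}$
for $\psi \in \{\mu, \sigma\}$. The log link for the residual SD is fixed
(no alternative links are implemented). The stacked random-effect vector
$b_i = (b_{i\mu 1}, \ldots, b_{i\mu K}, b_{i\sigma 1}, \ldots, b_{i\sigma K})$
is multivariate normal with unstructured covariance $\Sigma = T P T$, where
$T$ is the diagonal matrix of scales $\tau$ and $P$ a correlation matrix.
The default design is an intercept plus linear time in $X$ and a random
intercept in $Z$, for both submodels of every biomarker; arbitrary formulas
are accepted, and the math layer never hard-codes $K = 2$ (the testing
focus is bivariate, matching the implementation the model class originated
with).

Baseline covariates are centered by default (both submodels identically —
the sensible symmetric choice since they share the subject's covariate
vector), so intercepts are reported on the centered scale; `center = FALSE`
disables this. The time variable is never centered.

**Event submodel.** With $\mathcal{L}_i(t)$ the longitudinal history,
$$
h_i(t) = \exp\!\big(\log h_0(t) + w_i^\top \gamma +
\eta_{i\alpha}(\mathcal{L}_i(t); t)\big),
$$
where $\log h_0(t) = \sum_{\ell=1}^{L} \gamma_{h0,\ell} B_\ell(t)$ is a
penalized B-spline expansion (default $L = 6$ cubic basis functions,
equally spaced knots over $[0, \max T_i]$ with coincident boundary knots;
the basis is clamped to its boundary values outside the span). Three
association structures are supported:

* **CV** (current value): $\sum_k \alpha_{\mu k}\,\eta_{i\mu k}(t) +
  \alpha_{\sigma k} \exp(\eta_{i\sigma k}(t))$ — the variability enters on
  the SD scale, i.e. `exp` of the scale predictor, not the variance scale;
* **LP** (linear predictor): the same with $\eta_{i\sigma k}(t)$ in place of
  $\exp(\eta_{i\sigma k}(t))$;
* **RE** (random effects): $\alpha^\top b_i$, constant in time.

**Likelihood.** Conditional on $b_i$, longitudinal and event processes are
independent and repeated measurements are independent, so the joint
likelihood factorises into the per-observation Gaussian terms and the
standard survival term
$\delta_i \log h_i(T_i) - \int_{e_i}^{T_i} h_i(s)\,ds$, where $e_i$ is the
entry (left-truncation) time. The integral is approximated by a single
15-node Gauss–Kronrod panel mapped affinely onto $[e_i, T_i]$; any other
node count $Q \geq 7$ falls back to Gauss–Legendre. A single panel matches
how the quadrature is conventionally used in joint models and makes the
cumulative hazard exactly interval-additive at the quadrature level. When
the association varies with time, the longitudinal design is re-evaluated
at the node times with all baseline covariates held at their subject values.

**Priors.** Normal$(0, 10)$ on all fixed effects ($\beta$, $\gamma$,
$\alpha$); half-$t(3, 2.5)$ on the random-effect SDs; LKJ$(1)$ on $P$;
for the spline coefficients the Bayesian P-spline prior
$p(\gamma_{h0} \mid \tau_h) \propto \tau_h^{\rho/2}
\exp\{-\tfrac{\tau_h}{2}\, \gamma_{h0}^\top \Delta_r^\top \Delta_r
\gamma_{h0}\}$ with difference order $r = 2$ (standard P-spline practice)
and penalty rank $\rho = L - r$; and Beta$(1, 1)$ on the smoothing
parameter $\tau_h$, which is therefore bounded in $(0,1)$ exactly as the
model treats it. The hyperparameters are package defaults, all
configurable via `jm_priors()`; the bounded smoothing parameter has modest
reach, so an optional multiplier could be added by rescaling the penalty —
we keep the stated form. The P-spline prior is partially improper
(coefficient trends of degree $< r$ are unpenalized); the likelihood
identifies those directions through the event counts and their time trend.

## Estimation

The joint posterior is coded once as a C++ template differentiated by
`TMB`; a No-U-Turn sampler (multinomial variant, dual-averaging step-size
adaptation, windowed metric estimation) written in R consumes the gradient.
Three reparameterisations matter for the sampler geometry:

* **Non-centered random effects**: the sampler draws standard-normal
  innovations $z_i$ and sets $b_i = T\,\mathrm{chol}(P)\, z_i$ — the
  standard remedy for hierarchical scale funnels.
* **Vine parameterisation of $P$**: the canonical partial correlations of a
  C-vine are independent shifted-Beta variables under the LKJ law
  ($x \sim 2\,\mathrm{Beta}(a_m, a_m) - 1$ with $a_m = \eta + (d-1-m)/2$ at
  vine level $m$), so $P$ is sampled through $\tanh$-unconstrained partial
  correlations with exact prior and trivial Jacobian. Tests verify the
  implied Beta$(d/2, d/2)$ marginal of each correlation.
* **Centered association designs**: the fixed-design columns of the
  association predictors (and the event covariates) are centered at their
  data means, so the baseline spline represents the log hazard at the
  average predictor. Without this, the spline level is strongly
  anti-correlated with $\alpha \times (\text{mean predictor})$ and
  trajectories become very long. The reparameterisation leaves $\alpha$,
  $\gamma$ and $\beta$ untouched; for the CV structure only the $\mu$ part
  is centered (centering inside the exponential would rescale
  $\alpha_\sigma$ and hence change its prior). Predictions apply the same
  centering, so the hazard is invariant.

The metric is diagonal over the innovations and *dense* over the model
parameters (a few dozen), whose posterior cross-correlations otherwise
force maximum-depth trajectories. Initial values are jittered uniforms in
the unconstrained space, except the spline coefficients, which start at the
crude log event rate — with centered designs that is the posterior
neighbourhood, and starting a partially improper prior direction at an
extreme value wastes most of a short warmup (this is the one deliberate
departure from purely default initialisation).

Defaults are 2 chains of 1000 warmup + 1000 sampling iterations. Each fit
reports split-R-hat for every sampled scalar, effective sample sizes
(via `coda`), divergence and tree-depth saturation counts. Per-subject
log-likelihood contributions (the subject's longitudinal terms plus the
event term, *conditional* on the subject's drawn random effects) are stored
for PSIS-LOO; marginal (random-effects-integrated) LOO is out of scope, and
the conditional choice is the common joint-model practice.

The constant-variance comparator (`jmwiv_constvar()`, or
`constant_variance = TRUE`) is the same model with the log-SD submodel
reduced to a single intercept per biomarker, no $\sigma$ random effects and
no $\sigma$ association terms — the standard joint model whose neglect of
WIV the package is designed to expose.

## The simulator

`jm_simulate()` generates from a Cox-Exponential joint model with LP
association and the intercept + slope / random-intercept MELSM: covariates
$w_1 \sim \mathrm{Bernoulli}(0.5)$, $w_2 \sim N(0,1)$; random effects
$b_i \sim N_4(0, TPT)$; and, because the LP association composed with the
intercept + slope predictors collapses the log hazard to a linear function
of time, event times invert in closed form,
$$
T_i = \frac{1}{B}\log\!\Big(1 - \frac{B \log U_i}
{\lambda e^{w_i^\top\gamma + A_i}}\Big),
\qquad
A_i = \sum_k \alpha_{\mu k}(\beta_{0\mu k} + b_{i\mu k}) +
\alpha_{\sigma k}(\beta_{0\sigma k} + b_{i\sigma k}),
$$
$B = \sum_k \alpha_{\mu k}\beta_{1\mu k} + \alpha_{\sigma k}\beta_{1\sigma k}$,
with the exponential limit at $B = 0$ and `Inf` (the subject is censored)
when a negative $B$ caps the cumulative hazard below $-\log U_i$. Censoring
is Uniform$(0, T_{\max})$; visits run every 1 time unit from 0 up to the
observed time (never beyond it), so every subject has at least the baseline
visit and there is no immortal-time filtering.

The default configuration is the generating truth of the package's recovery
study: $\beta_{\mu 1} = (2.19, -0.04)$, $\beta_{\sigma 1} = (-1.36, -0.02)$,
$\beta_{\mu 2} = (1.04, 0.35)$, $\beta_{\sigma 2} = (0.16, 0.01)$,
$\tau = (0.81, 0.52, 0.44, 0.16)$, $\gamma = (0.93, -2.3)$,
$\alpha = (-2.24, 0.55, 1.9, 0.35)$. The correlation matrix sets
$\rho(\mu_1,\mu_2) = 0.5$ and $\rho(\mu_k, \sigma_k) = 0.4$ — positive
mean–mean and mean–variability correlations of the kind seen in lung
function and BMI registries — with other pairs zero. $T_{\max} = 10$ and
$\lambda = 10$ were chosen once so that roughly a third of subjects die
during follow-up with on average four visits; the numerically large
$\lambda$ simply offsets the strongly negative association intercept
($A_i \approx -6.9$ at $b = 0$) implied by the other defaults.

What the simulator does *not* emulate: informative visit schedules,
left-truncated entry (left truncation is exercised directly in the hazard
tests), measurement error distinct from WIV, non-Gaussian outcomes, or
competing risks. Passing recovery tests on these data therefore says
nothing about those features of real registries.

## Evaluation harness

`run_simulation_study()` replays the recovery design: per replicate it
simulates, fits the requested models, and records posterior means, 95%
credible intervals and optionally PSIS-LOO; aggregation yields, per
parameter, the mean and SD (eSD) of the posterior means and the empirical
coverage. Replicate $r$ uses seed `base_seed + r`, making results
invariant to execution order. Failed fits are recorded and excluded, never
silently dropped.

Two qualitative signatures distinguish the models on heteroscedastic data:
the comparator's $\sigma$ intercept absorbs the *marginal* residual spread
(close to $\tfrac12 \log E[\sigma^2]$, i.e. well above the conditional
intercept), and its event-submodel coefficients — particularly the
continuous baseline covariate and the mean associations — are attenuated
with far-below-nominal coverage. PSIS-LOO (implemented in the package:
Zhang–Stephens generalized-Pareto tail fit with the usual weak shrinkage
of the shape, smoothing of the top $\min(0.2S, 3\sqrt S)$ weights, per-unit
Pareto-$k$ diagnostics) orders the models by conditional ELPD.

## Numerical choices and problem sizes

* Gauss–Kronrod 15 abscissae/weights are hard-coded constants; the rule is
  exact for the constant-hazard case and reproduces the log-linear
  closed form to $10^{-10}$ relative error, which the tests assert.
* Spline evaluation clamps times to the knot span; prediction grids outside
  the span are rejected.
* `exp` overflow in the residual-SD link is guarded at $e^{700}$;
  out-of-support parameters give $-\infty$ posterior density by contract.
* Divergences are declared at an energy error of 1000, as in mainstream
  HMC implementations; step-size adaptation targets acceptance 0.8.
* Ties in visit times are allowed (rows are ordered within subject);
  duplicate `(id, time, biomarker)` rows are schema errors.

The test suite runs the recovery study at a deliberately desk-sized scale —
3 replicates of $N = 500$ with one chain of 250 warmup + 100 sampling
iterations and tree depth capped at 7, plus a 6-replicate, $N = 200$
coverage check with 150 + 100 iterations — sizes chosen so the full suite
completes on a single CPU in well under half an hour while still exercising
every stage of the pipeline. Warmup dominates that budget deliberately:
with these posteriors, 150-iteration warmups leave the event block visibly
short of its mode, while 250 suffice. At these chain lengths split-R-hat values around 1.1–1.5 on the
weakly identified association coefficients are expected and tolerated in
the study fits; publication-grade inference should use the package
defaults (2 × 1000 + 1000), for which the diagnostics gate is R-hat
$\leq 1.05$. The replicate spread at reduced scale is accordingly wider
than the full-scale study's, and the tests' tolerance bands widen by the
Monte-Carlo factors $\sqrt{1000/N}$ and $1/\sqrt{R}$.

## Known limitations

* The WIV is not distinguishable from measurement error; if the biomarker
  is noisily measured, the variability association is attenuated.
* The per-subject conditional likelihood used for LOO favours neither model
  by construction, but it is not the marginal predictive density.
* Estimation cost grows quickly with the number of biomarkers and random
  effects (an unstructured $P$ has $O(K^2)$ parameters); a moderate number
  of biomarkers and parsimonious random effects are recommended.
* The baseline spline extends as a constant beyond the last observed event
  time; extrapolated survival curves should not be over-read.
* Only Gaussian outcomes are supported; location-scale families beyond the
  normal would require a different likelihood and a rethought definition
  of WIV.
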