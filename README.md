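# jmwiv

Bayesian joint models for a time-to-event outcome and multiple longitudinal
biomarkers in which the hazard depends on the biomarkers'
**within-individual variability (WIV)** as well as on their means.

Two-stage analyses that summarise a patient's biomarker fluctuation by a
per-subject standard deviation and enter it into a Cox model suffer
regression dilution, ignore time trends in the variability, and invite
immortal-time bias when subjects with few visits are dropped. `jmwiv` fits
the one-stage alternative: a **mixed-effects location-scale model** (MELSM)
for the longitudinal outcomes,

```
y_ijk ~ N( eta_mu_ik(t_ij) ,  sigma_ijk^2 ),      log sigma_ijk = eta_sigma_ik(t_ij),
eta_psi_ik(t) = X(t) beta_psi_k + Z(t) b_i_psi_k,      b_i ~ N(0, T P T),
```

coupled to a proportional-hazards event submodel with a penalized B-spline
log baseline hazard and Gauss–Kronrod cumulative-hazard quadrature with
delayed-entry support,

```
h_i(t) = exp( log h0(t) + w_i' gamma + eta_alpha_i(t) ),
```

where the association `eta_alpha_i(t)` is a function of the current values
(`cv`), the current linear predictors (`lp`), or the random effects (`re`)
of both the mean and the variability submodels. Estimation is Hamiltonian
Monte Carlo (a No-U-Turn sampler over gradients autodiffed through `TMB`),
with non-centered random effects, an LKJ-distributed correlation matrix
sampled through vine partial correlations, and a Bayesian P-spline prior on
the baseline hazard. The package also provides the Cox-Exponential
simulator for this model class, PSIS-LOO model comparison, and a
simulation-study harness (bias, eSD, coverage, ELPD).

## Worked example

```r
library(jmwiv)

# simulate a joint dataset from the default generating truth
dat <- jm_simulate(sim_config(n_subjects = 300L), seed = 1)

# fit the location-scale joint model with the linear-predictor association
fit <- jmwiv(dat$long, dat$surv, association = "lp",
             chains = 1, warmup = 300, sampling = 300, seed = 1)
summarise_fit(fit)[9:14, c("parameter", "mean", "sd", "q2.5", "q97.5")]
```

```
      parameter    mean     sd    q2.5  q97.5
9      gamma_w1  1.0167 0.4013  0.3288  1.815
10     gamma_w2 -2.7904 0.4583 -3.8300 -2.040
11    alpha_mu1 -2.7492 0.8156 -4.7368 -1.369
12    alpha_mu2  0.1636 1.2926 -2.4848  2.546
13 alpha_sigma1  3.6495 1.5736  1.1179  6.886
14 alpha_sigma2  3.3579 5.2243 -5.1119 13.567
```

The generating values were `gamma = (0.93, -2.3)` and
`alpha = (alpha_mu1, alpha_mu2, alpha_sigma1, alpha_sigma2) =
(-2.24, 0.55, 1.9, 0.35)`: every 95% credible interval covers its
generating value at this modest sample size (about 100 events), and — the
point of the model — the interval for the association between the
*variability* of biomarker 1 and the hazard (`alpha_sigma1`) lies entirely
above zero. A constant-variance fit of the same data (`jmwiv_constvar()`)
cannot estimate the `alpha_sigma` terms and attenuates `gamma_w2` and
`alpha_mu1`; its predictive performance is correspondingly worse:

```r
fit_cv <- jmwiv_constvar(dat$long, dat$surv, association = "lp",
                         chains = 1, warmup = 300, sampling = 300, seed = 1)
loo_difference(compute_loo(fit), compute_loo(fit_cv))
#> $elpd_diff [1] 151.4    $se_diff [1] 23.1
#> (positive: the location-scale model predicts better)
```

`predict_trajectory()` returns each subject's posterior mean curve with its
WIV band `eta_mu(t) ± 1.96 exp(eta_sigma(t))`; `predict_survival()` returns
posterior survival curves from the subject's own random effects.
`run_simulation_study()` replays the full recovery design (replicated
simulate/fit/aggregate with coverage and ELPD tables). A thin command-line
wrapper with `simulate`, `fit`, `fit-cv`, `loo`, `simstudy` and `predict`
subcommands is installed under `inst/cli/jmwiv.R`.

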