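test_that("subject frame draws covariates and random effects correctly", {
  cfg <- sim_config(n_subjects = 500L, w1_prob = 1)
  set.seed(10)
  fr <- draw_subject_frame(cfg)
  expect_true(all(fr$w[, "w1"] == 1))
  # degenerate scales give zero random effects
  cfg0 <- sim_config(n_subjects = 50L, tau = rep(1e-12, 4))
  set.seed(10)
  expect_equal(max(abs(draw_subject_frame(cfg0)$b)), 0, tolerance = 1e-10)
})

test_that("random-effect draws have covariance TPT", {
  cfg <- sim_config(n_subjects = 20000L)
  set.seed(11)
  b <- draw_subject_frame(cfg)$b
  Sigma <- assemble_covariance(cfg$tau, cfg$corr)
  emp <- cov(b)
  # entrywise within 3 Monte Carlo standard errors (normal fourth moments)
  n <- nrow(b)
  for (i in 1:4) for (j in 1:4) {
    se <- sqrt((Sigma[i, i] * Sigma[j, j] + Sigma[i, j]^2) / n)
    expect_lt(abs(emp[i, j] - Sigma[i, j]), 3 * se)
  }
})

test_that("log-hazard intercept and slope match direct substitution", {
  cfg <- sim_config()
  # zero association removes the longitudinal contribution
  cfg0 <- cfg; cfg0$alpha <- rep(0, 4)
  hz0 <- linear_hazard_terms(cfg0, rnorm(4))
  expect_equal(hz0$A, 0); expect_equal(hz0$B, 0)
  # mean-only association on biomarker 1 at b = 0
  cfg1 <- cfg; cfg1$alpha <- c(1, 0, 0, 0)
  hz1 <- linear_hazard_terms(cfg1, rep(0, 4))
  expect_equal(hz1$A, 2.190)
  expect_equal(hz1$B, -0.040)
})

test_that("A and B reproduce the composed linear-predictor hazard", {
  cfg <- sim_config()
  set.seed(12)
  b <- drop(mvtnorm::rmvnorm(1, sigma = assemble_covariance(cfg$tau, cfg$corr)))
  wg <- 0.4
  hz <- linear_hazard_terms(cfg, b)
  tt <- runif(100, 0, 10)
  direct <- exp(log(cfg$lambda0) + wg + hz$A + hz$B * tt)
  eta_mu <- sapply(1:2, function(k)
    cfg$beta_mu[1, k] + b[k] + cfg$beta_mu[2, k] * tt)
  eta_sig <- sapply(1:2, function(k)
    cfg$beta_sigma[1, k] + b[2 + k] + cfg$beta_sigma[2, k] * tt)
  composed <- cfg$lambda0 * exp(wg +
    association_predictor("lp", cfg$alpha[c(1, 2, 3, 4)], eta_mu, eta_sig))
  expect_equal(direct, composed, tolerance = 1e-12)
})

test_that("event-time inversion solves the cumulative hazard equation", {
  cfg <- sim_config(lambda0 = 0.1)
  # u = 1 gives an immediate event time of zero
  expect_equal(invert_event_time(1, cfg, 0, 0.1, 0), 0)
  # exponential quantile when B = 0
  cfg2 <- sim_config(lambda0 = 0.5)
  expect_equal(invert_event_time(exp(-1), cfg2, 0, 0, 0), 2, tolerance = 1e-12)
  # numeric root for lambda = 0.1, B = 0.1, u = 0.5: solves
  # (lambda/B)(e^{BT} - 1) = -log u, i.e. T = 10 log(1 + log 2) = 5.26589
  got <- invert_event_time(0.5, cfg, 0, 0.1, 0)
  root <- uniroot(function(T) (0.1 / 0.1) * (exp(0.1 * T) - 1) + log(0.5),
                  c(0, 50), tol = 1e-12)$root
  expect_equal(got, root, tolerance = 1e-9)
  expect_equal(got, 5.26589, tolerance = 1e-5)
  # negative slope: the event may never happen
  expect_identical(invert_event_time(0.5, cfg, -3, -0.5, -2), Inf)
})

test_that("censoring takes the minimum and flags events", {
  cfg <- sim_config(t_max = 10)
  got <- apply_censoring(c(Inf, 0, 5), cfg, T_cens = c(3, 3, 3))
  expect_equal(got$time, c(3, 0, 3))
  expect_equal(got$event, c(0L, 1L, 0L))
  # empirical event probability matches a numeric integration oracle
  lam <- 0.3; tmax <- 10
  set.seed(13)
  n <- 20000L
  Tev <- rexp(n, lam)
  cfg3 <- sim_config(t_max = tmax)
  cc <- apply_censoring(Tev, cfg3)
  # P(delta = 1) = P(T <= U(0, tmax)) = int_0^tmax (1 - F(c))/tmax ... via 1D quadrature
  p_event <- integrate(function(cns) pexp(cns, lam) / tmax, 0, tmax)$value
  se <- sqrt(p_event * (1 - p_event) / n)
  expect_lt(abs(mean(cc$event) - p_event), 3 * se)
})

test_that("longitudinal schedule and noise follow the location-scale law", {
  cfg <- sim_config()
  set.seed(14)
  # short follow-up: only the baseline visit
  rows <- generate_longitudinal(1, 0.5, cfg, rep(0, 4))
  expect_equal(nrow(rows), 2L)          # one visit x two biomarkers
  expect_equal(unique(rows$time), 0)
  # noise scale shrinks to zero with the sigma intercept
  cfg0 <- cfg; cfg0$beta_sigma[1, ] <- -30
  rows0 <- generate_longitudinal(1, 3, cfg0, rep(0, 4))
  mu_expect <- ifelse(rows0$biomarker == 1,
                      2.19 - 0.04 * rows0$time, 1.04 + 0.35 * rows0$time)
  expect_equal(rows0$value, mu_expect, tolerance = 1e-8)
  # marginal SD of biomarker 1 at t = 0, b = 0 is exp(-1.360)
  set.seed(15)
  y0 <- replicate(20000, generate_longitudinal(1, 0.5, cfg, rep(0, 4))$value[1])
  expect_equal(sd(y0), exp(-1.36), tolerance = 0.01)
})

test_that("full simulation satisfies its structural invariants", {
  cfg <- sim_config(n_subjects = 200L)
  d <- jm_simulate(cfg, seed = 16)
  expect_true(all(d$surv$time <= cfg$t_max))
  expect_true(all(d$surv$event %in% 0:1))
  tmax_subj <- d$surv$time[match(d$long$id, d$surv$id)]
  expect_true(all(d$long$time <= tmax_subj))
  expect_true(all(table(d$long$id[d$long$biomarker == 1]) >= 1))
  # empty call
  e <- jm_simulate(sim_config(n_subjects = 0L), seed = 1)
  expect_null(e$long)
  # determinism
  d2 <- jm_simulate(cfg, seed = 16)
  expect_identical(d$long$value, d2$long$value)
  expect_identical(d$surv$time, d2$surv$time)
})

test_that("inverse-CDF identity ties the simulator to the quadrature", {
  cfg <- sim_config(n_subjects = 60L)
  d <- jm_simulate(cfg, seed = 17)
  tr <- d$truth
  for (i in seq_len(30)) {
    if (!is.finite(tr$event_time[i])) next
    hz <- function(t) cfg$lambda0 * exp(tr$wgamma[i] + tr$A[i] + tr$B * t)
    ch <- cumulative_hazard(0, tr$event_time[i], hz)
    expect_lt(abs(ch + log(tr$u[i])), 1e-8)
  }
})

test_that("event times with B = 0 are exponential within covariate strata", {
  cfg <- sim_config(n_subjects = 4000L, w1_prob = 0,
                    gamma = c(0, 0), alpha = rep(0, 4), lambda0 = 0.25)
  d <- jm_simulate(cfg, seed = 18)
  tr <- d$truth
  expect_equal(tr$B, 0)
  ks <- ks.test(tr$event_time, pexp, 0.25)
  expect_gt(ks$p.value, 0.01)
})
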