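make_theta <- function(designs, spline, jitter = 0) {
  K <- designs$K
  pmu <- sum(vapply(designs$mu, function(b) ncol(b$X), integer(1)))
  psig <- sum(vapply(designs$sigma, function(b) ncol(b$X), integer(1)))
  set.seed(100 + jitter)
  list(beta_mu = rnorm(pmu, 0, 0.3), beta_sigma = rnorm(psig, 0, 0.3),
       gamma_w = rnorm(2, 0, 0.3), alpha = rnorm(2 * K, 0, 0.3),
       gamma_h0 = rnorm(spline$L, -1, 0.3),
       tau = exp(rnorm(designs$n_re, -0.5, 0.2)),
       corr = jmwiv:::cpc_to_corr(tanh(rnorm(designs$n_re * (designs$n_re - 1) / 2,
                                             0, 0.3)), designs$n_re),
       tau_h = 0.4)
}

test_that("log posterior decomposes into its documented terms", {
  d <- small_data(8L, seed = 55L)
  designs <- jm_designs(d$long, center = FALSE)
  spline <- bh_spline(c(0, max(d$surv$time)))
  priors <- jm_priors()
  theta <- make_theta(designs, spline)
  theta$alpha <- rep(0, 4)                      # association off
  set.seed(101)
  b <- matrix(rnorm(designs$N * 4, 0, 0.2), designs$N, 4)
  lp <- jm_log_posterior(theta, b, d$long, d$surv, designs, spline, "lp",
                         priors, gk_rule(), ~ w1 + w2)
  # term-by-term oracle
  surv <- d$surv
  ll_long <- 0
  off <- jmwiv:::re_offsets(designs)
  for (k in 1:2) {
    blk <- designs$mu[[k]]; blks <- designs$sigma[[k]]
    eta_mu <- linear_predictor(blk, theta$beta_mu[(2 * k - 1):(2 * k)],
                               b[, off$mu[k] + 1, drop = FALSE])
    eta_sig <- linear_predictor(blks, theta$beta_sigma[(2 * k - 1):(2 * k)],
                                b[, off$sigma[k] + 1, drop = FALSE])
    ll_long <- ll_long + sum(longitudinal_loglik(d$long$value[blk$rows],
                                                 eta_mu, eta_sig))
  }
  wg <- as.matrix(surv[, c("w1", "w2")]) %*% theta$gamma_w
  ll_ev <- sum(vapply(seq_len(designs$N), function(i)
    event_loglik(surv$entry[i], surv$time[i], surv$event[i],
                 function(t) hazard_at(t, spline, theta$gamma_h0, wg[i])),
    numeric(1)))
  Sigma <- assemble_covariance(theta$tau, theta$corr)
  ll_b <- sum(mvtnorm::dmvnorm(b, sigma = Sigma, log = TRUE))
  lp_prior <- sum(dnorm(c(theta$beta_mu, theta$beta_sigma), 0, 10, log = TRUE)) +
    sum(dnorm(theta$gamma_w, 0, 10, log = TRUE)) +
    sum(dnorm(theta$alpha, 0, 10, log = TRUE)) +
    pspline_log_prior(theta$gamma_h0, theta$tau_h, spline) +
    sum(jmwiv:::half_t_lpdf(theta$tau, 3, 2.5)) +
    dbeta(theta$tau_h, 1, 1, log = TRUE)
  expect_equal(lp, ll_long + ll_ev + ll_b + lp_prior, tolerance = 1e-8)
})

test_that("out-of-support parameters give -Inf", {
  d <- small_data(8L, seed = 55L)
  designs <- jm_designs(d$long, center = FALSE)
  spline <- bh_spline(c(0, max(d$surv$time)))
  theta <- make_theta(designs, spline)
  b <- matrix(0, designs$N, 4)
  bad <- theta; bad$tau[2] <- 0
  expect_identical(jm_log_posterior(bad, b, d$long, d$surv, designs, spline,
                                    "lp"), -Inf)
  bad <- theta; bad$tau_h <- 1.2
  expect_identical(jm_log_posterior(bad, b, d$long, d$surv, designs, spline,
                                    "lp"), -Inf)
  bad <- theta; bad$corr <- matrix(c(1, 2, 2, 1), 2)
  expect_identical(jm_log_posterior(bad, b[, 1:2], d$long, d$surv,
                                    jm_designs(d$long, sigma_random = ~0,
                                               center = FALSE),
                                    spline, "lp"), -Inf)
})

test_that("compiled objective agrees with the reference log posterior", {
  d <- small_data(12L, seed = 56L)
  designs <- jm_designs(d$long, center = FALSE)
  spline <- bh_spline(c(0, max(d$surv$time)))
  priors <- jm_priors()
  rule <- gk_rule()
  for (assoc in c("lp", "cv")) {
    inputs <- jmwiv:::build_tmb_inputs(d$long, d$surv, designs, spline, assoc,
                                       priors, rule, ~ w1 + w2)
    obj <- jmwiv:::make_objective(inputs)
    pidx <- split(seq_along(names(obj$par)), names(obj$par))
    nre <- designs$n_re
    set.seed(200)
    for (rep in 1:3) {
      p <- obj$par + runif(length(obj$par), -0.4, 0.4)
      theta <- list(beta_mu = p[pidx$beta_mu], beta_sigma = p[pidx$beta_sig],
                    gamma_w = p[pidx$gamma_w], alpha = p[pidx$alpha],
                    gamma_h0 = p[pidx$gamma_h0], tau = exp(p[pidx$log_tau]),
                    corr = jmwiv:::cpc_to_corr(tanh(p[pidx$z_cpc]), nre),
                    tau_h = plogis(p[pidx$logit_tau_h]))
      braw <- matrix(p[pidx$b_raw], designs$N, nre)
      b <- t(diag(theta$tau) %*% t(chol(theta$corr)) %*% t(braw))
      lp_r <- jm_log_posterior(theta, b, d$long, d$surv, designs, spline,
                               assoc, priors, rule, ~ w1 + w2,
                               centers = inputs$centers)
      # the compiled objective works on the unconstrained scale: add the
      # innovation density and transform Jacobians to the reference value
      Sigma <- assemble_covariance(theta$tau, theta$corr)
      adj <- sum(dnorm(braw, log = TRUE)) -
        sum(mvtnorm::dmvnorm(b, sigma = Sigma, log = TRUE)) +
        sum(p[pidx$log_tau]) + log(theta$tau_h * (1 - theta$tau_h)) +
        jmwiv:::lkj_cpc_log_prior(p[pidx$z_cpc], nre, 1)
      expect_equal(-obj$fn(p), unname(lp_r + adj), tolerance = 1e-7)
    }
  }
})

test_that("gradient of the compiled objective matches finite differences", {
  skip_if_not_installed("numDeriv")
  d <- small_data(6L, seed = 57L)
  designs <- jm_designs(d$long, center = FALSE)
  spline <- bh_spline(c(0, max(d$surv$time)))
  inputs <- jmwiv:::build_tmb_inputs(d$long, d$surv, designs, spline, "lp",
                                     jm_priors(), gk_rule(), ~ w1 + w2)
  obj <- jmwiv:::make_objective(inputs)
  set.seed(201)
  p <- obj$par + runif(length(obj$par), -0.3, 0.3)
  g_ad <- obj$gr(p)
  g_fd <- numDeriv::grad(obj$fn, p, method = "simple",
                         method.args = list(eps = 1e-7))
  expect_equal(drop(g_ad), g_fd, tolerance = 1e-3)
})
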