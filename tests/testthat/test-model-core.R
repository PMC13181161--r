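make_long <- function() {
  jm_longitudinal(data.frame(
    id = rep(1:3, each = 6),
    time = rep(c(0, 1, 2), times = 6),
    biomarker = rep(rep(1:2, each = 3), times = 3),
    value = rnorm(18),
    x = rep(c(0.2, -0.4, 1.1), each = 6)))
}

test_that("design construction gives the documented default structure", {
  set.seed(1)
  long <- make_long()
  d <- jm_designs(long, center = FALSE)
  expect_equal(d$K, 2L)
  expect_equal(d$N, 3L)
  # intercept + time in X, random intercept in Z, per submodel and biomarker
  for (blk in c(d$mu, d$sigma)) {
    expect_equal(ncol(blk$X), 2L)
    expect_equal(unname(blk$X[, 1]), rep(1, 9))
    expect_equal(unname(blk$X[, 2]), rep(c(0, 1, 2), 3))
    expect_equal(ncol(blk$Z), 1L)
  }
  expect_equal(d$n_re, 4L)
  # intercept-only design: a column of ones
  d0 <- jm_designs(long, mu_fixed = ~1)
  expect_equal(unname(d0$mu[[1]]$X), matrix(1, 9, 1), ignore_attr = TRUE)
  expect_error(jm_designs(long, mu_fixed = ~nope), "unknown covariate")
})

test_that("covariate centering shifts only non-time columns", {
  set.seed(2)
  long <- make_long()
  d <- jm_designs(long, mu_fixed = ~ time + x)
  expect_equal(mean(d$mu[[1]]$X[, "x"]), 0, tolerance = 1e-12)
  expect_equal(unname(d$mu[[1]]$X[, "time"]), rep(c(0, 1, 2), 3))
  d_raw <- jm_designs(long, mu_fixed = ~ time + x, center = FALSE)
  expect_equal(unname(d_raw$mu[[1]]$X[, "x"]), rep(c(0.2, -0.4, 1.1), each = 3))
})

test_that("linear predictor adds the subject's own random effects", {
  set.seed(3)
  long <- make_long()
  d <- jm_designs(long, center = FALSE)
  blk <- d$mu[[1]]
  # zero parameters give zero
  expect_equal(linear_predictor(blk, c(0, 0), matrix(0, 3, 1)), rep(0, 9))
  # intercept-only with one subject effect
  d0 <- jm_designs(long, mu_fixed = ~1)
  b <- matrix(c(0.5, 0, 0), 3, 1)
  eta <- linear_predictor(d0$mu[[1]], 2.190, b)
  expect_equal(eta[1:3], rep(2.690, 3))
  # intercept + time at t = 10 with b = 0: 2.190 - 0.040 * 10
  blk10 <- blk; blk10$X <- cbind(1, 10)
  expect_equal(linear_predictor(blk10, c(2.190, -0.040), matrix(0, 3, 1))[1],
               1.790)
  # linearity: eta(b1 + b2, b) = eta(b1, b) + eta(b2, 0)
  b1 <- rnorm(2); b2 <- rnorm(2); bm <- matrix(rnorm(3), 3, 1)
  expect_equal(linear_predictor(blk, b1 + b2, bm),
               linear_predictor(blk, b1, bm) + linear_predictor(blk, b2, 0 * bm))
  expect_error(linear_predictor(blk, 1, bm), "beta length")
})

test_that("random-effects covariance assembles and round-trips", {
  expect_equal(assemble_covariance(rep(1, 4), diag(4)), diag(4))
  P2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  S2 <- assemble_covariance(c(2, 3), P2)
  expect_equal(S2, matrix(c(4, 3, 3, 9), 2))
  # scales from the recovery study: squares on the diagonal under independence
  tau <- c(0.810, 0.520, 0.440, 0.160)
  S <- assemble_covariance(tau, diag(4))
  expect_equal(diag(S), c(0.6561, 0.2704, 0.1936, 0.0256))
  # round trip to machine precision
  P <- default_sim_corr()
  S <- assemble_covariance(tau, P)
  back <- jmwiv:::cov_to_scales(S)
  expect_equal(back$tau, tau, tolerance = 1e-14)
  expect_equal(back$corr, P, tolerance = 1e-14)
  expect_error(assemble_covariance(c(-1, 1), diag(2)), "positive")
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(assemble_covariance(c(1, 1), bad), "positive definite")
})

test_that("residual SD applies the log link inverse", {
  expect_equal(residual_sd(0), 1)
  expect_equal(residual_sd(log(2)), 2)
  expect_equal(residual_sd(-1.360), exp(-1.360))
  expect_equal(residual_sd(-1.360), 0.2567, tolerance = 1e-3)
  expect_true(is.finite(residual_sd(1e4)))
})

test_that("location-scale log-likelihood matches its closed form", {
  # exact residual: -log(2*pi)/2
  expect_equal(longitudinal_loglik(1.3, 1.3, 0), -0.918939, tolerance = 1e-6)
  # one-sigma residual for any sigma
  for (es in c(-1, 0, 0.7)) {
    expect_equal(longitudinal_loglik(exp(es), 0, es),
                 -0.5 * log(2 * pi) - es - 0.5, tolerance = 1e-12)
  }
  expect_equal(longitudinal_loglik(1, 0, log(2)),
               -0.5 * log(2 * pi) - log(2) - 0.125, tolerance = 1e-12)
  expect_equal(longitudinal_loglik(1, 0, log(2)), -1.73709, tolerance = 1e-5)
  expect_error(longitudinal_loglik(1:3, 1:2, 1:3), "equal length")
})

test_that("constant log-SD reduces to the ordinary Gaussian density", {
  set.seed(9)
  y <- rnorm(20); mu <- rnorm(20); s <- 1.7
  expect_equal(longitudinal_loglik(y, mu, rep(log(s), 20)),
               dnorm(y, mu, s, log = TRUE), tolerance = 1e-12)
})
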