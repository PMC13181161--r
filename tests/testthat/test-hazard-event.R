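test_that("association structures compute their documented forms", {
  em <- matrix(c(2, 1), 1); es <- matrix(c(-1.36, 0.2), 1)
  # zero coefficients give zero for every structure
  expect_equal(association_predictor("cv", rep(0, 4), em, es), 0)
  expect_equal(association_predictor("lp", rep(0, 4), em, es), 0)
  expect_equal(association_predictor("re", rep(0, 3), b = rnorm(3)), 0)
  # LP with one biomarker, coefficients from the recovery truth
  got <- association_predictor("lp", c(-2.240, 1.900),
                               matrix(2), matrix(-1.36))
  expect_equal(got, -4.48 - 2.584, tolerance = 1e-12)
  # CV: the SD enters on its own scale, exp(0) = 1
  got <- association_predictor("cv", c(0, 3.3), matrix(5), matrix(0))
  expect_equal(got, 3.3)
  # RE: inner product with the random effects, constant in time
  b <- c(0.3, -0.2, 0.1, 0)
  expect_equal(association_predictor("re", c(1, 2, 3, 4), b = b),
               sum(c(1, 2, 3, 4) * b))
  expect_error(association_predictor("re", 1:4), "random effects")
  expect_error(association_predictor("lp", 1:3, em, es), "components")
})

test_that("hazard is log-linear in its components", {
  sp <- bh_spline(c(0, 10))
  lam <- 0.25
  g0 <- rep(log(lam), 6)
  tt <- seq(0.5, 9.5, length.out = 11)
  expect_equal(hazard_at(tt, sp, g0), rep(lam, 11), tolerance = 1e-12)
  # proportional hazards: shifting w'gamma by log 2 doubles the hazard
  h1 <- hazard_at(tt, sp, g0, wgamma = 0.4)
  h2 <- hazard_at(tt, sp, g0, wgamma = 0.4 + log(2))
  expect_equal(h2 / h1, rep(2, 11), tolerance = 1e-12)
  # the simulator's log-linear form exp(A' + B t) is representable
  A <- -1.1; B <- 0.248
  ha <- hazard_at(tt, sp, g0, wgamma = A - log(lam), eta_alpha = B * tt)
  expect_equal(ha, exp(A + B * tt), tolerance = 1e-12)
})

test_that("hazard ratio between subjects differing in w is time-constant", {
  sp <- bh_spline(c(0, 8), L = 7L)
  g0 <- rnorm(7)
  tt <- seq(0.2, 7.8, length.out = 25)
  r <- hazard_at(tt, sp, g0, wgamma = 1.3) / hazard_at(tt, sp, g0, wgamma = -0.2)
  expect_equal(r, rep(exp(1.5), 25), tolerance = 1e-12)
})

test_that("event log-likelihood matches closed forms and a dense oracle", {
  lam <- 0.6
  hz <- function(t) rep(lam, length(t))
  # censored, constant hazard, delayed entry
  expect_equal(event_loglik(1, 4, 0, hz), -lam * 3, tolerance = 1e-12)
  # event, constant hazard: log lambda - lambda T
  expect_equal(event_loglik(0, 2.5, 1, hz), log(lam) - lam * 2.5,
               tolerance = 1e-12)
  # exponential-model equivalence for a batch of records
  set.seed(4)
  for (i in 1:5) {
    Tm <- runif(1, 0.5, 6); dl <- rbinom(1, 1, 0.5)
    expect_equal(event_loglik(0, Tm, dl, hz),
                 dl * log(lam) - lam * Tm, tolerance = 1e-12)
  }
  # spline hazard vs dense trapezoid integration
  sp <- bh_spline(c(0, 6), L = 6L)
  g0 <- c(-1.5, -1.35, -1.2, -1.0, -1.1, -1.2)
  hsp <- function(t) hazard_at(t, sp, g0, wgamma = 0.3)
  grid <- seq(0, 5, length.out = 1e5)
  trap <- sum((hsp(grid)[-1] + hsp(grid)[-1e5]) / 2 * diff(grid))
  expect_equal(event_loglik(0, 5, 1, hsp), log(hsp(5)) - trap,
               tolerance = 1e-6)
  expect_error(event_loglik(0, 1, 2, hz), "event")
})
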