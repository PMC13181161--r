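# shared fixtures, all generated in code

# small joint dataset used across test files (cached per test run)
.fixture_env <- new.env(parent = emptyenv())

small_data <- function(n = 60L, seed = 404L, ...) {
  key <- paste0("d", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- sim_config(n_subjects = n, ...)
    .fixture_env[[key]] <- jm_simulate(cfg, seed = seed)
  }
  .fixture_env[[key]]
}

# one tiny fitted model reused by the fit/predict/loo tests
small_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    d <- small_data(40L, seed = 77L)
    .fixture_env$fit <- jmwiv(d$long, d$surv, association = "lp",
                              chains = 1L, warmup = 120L, sampling = 120L,
                              seed = 99L, max_treedepth = 6L, center = FALSE)
  }
  .fixture_env$fit
}

# two-subject hand-written joint dataset for i/o tests
toy_tables <- function() {
  long <- data.frame(
    id = c(1, 1, 1, 1, 2, 2),
    time = c(0, 1, 0, 1, 0, 0),
    biomarker = c(1, 1, 2, 2, 1, 2),
    value = c(2.1, 2.0, 1.1, 1.4, 3.0, 0.9))
  surv <- data.frame(id = c(1, 2), entry = c(0, 0), time = c(1.5, 0.4),
                     event = c(1, 0), w1 = c(0, 1), w2 = c(0.3, -1.2))
  list(long = long, surv = surv)
}
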