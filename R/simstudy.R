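#' Empirical coverage of a set of credible intervals
#'
#' @param intervals Matrix (replicates x 2) of interval endpoints, or a data
#'   frame with columns `lower`, `upper`.
#' @param truth The generating value.
#' @return Fraction of intervals containing `truth`.
#' @export
coverage <- function(intervals, truth) {
  if (is.data.frame(intervals))
    intervals <- cbind(intervals$lower, intervals$upper)
  intervals <- matrix(intervals, ncol = 2)
  if (nrow(intervals) == 0L) stop("no intervals supplied")
  mean(intervals[, 1] <= truth & truth <= intervals[, 2])
}

# generating values of the simulator, named like the fitted parameters
sim_truth <- function(config) {
  c(beta_mu1_Intercept = config$beta_mu[1, 1], beta_mu1_time = config$beta_mu[2, 1],
    beta_mu2_Intercept = config$beta_mu[1, 2], beta_mu2_time = config$beta_mu[2, 2],
    beta_sigma1_Intercept = config$beta_sigma[1, 1],
    beta_sigma1_time = config$beta_sigma[2, 1],
    beta_sigma2_Intercept = config$beta_sigma[1, 2],
    beta_sigma2_time = config$beta_sigma[2, 2],
    tau_mu1 = config$tau[1], tau_mu2 = config$tau[2],
    tau_sigma1 = config$tau[3], tau_sigma2 = config$tau[4],
    gamma_w1 = config$gamma[1], gamma_w2 = config$gamma[2],
    alpha_mu1 = config$alpha[1], alpha_mu2 = config$alpha[2],
    alpha_sigma1 = config$alpha[3], alpha_sigma2 = config$alpha[4])
}

#' Scenario template with a near-null variability association
#'
#' The default recovery scenario with the WIV contribution to the hazard set
#' close to zero; provided as a configuration template (no reference results
#' are attached to it).
#' @param alpha_sigma Length-2 WIV association coefficients (default
#'   `c(0.1, 0.05)`).
#' @export
sim_config_wiv_null <- function(alpha_sigma = c(0.1, 0.05)) {
  cfg <- sim_config()
  cfg$alpha[3:4] <- alpha_sigma
  cfg
}

#' Run a replicated parameter-recovery and model-comparison study
#'
#' For each replicate: simulate a dataset from `config`, fit the requested
#' models, and record posterior means, 95% credible intervals and (optionally)
#' PSIS-LOO. Aggregates into a per-parameter table — truth, mean of posterior
#' means, SD of posterior means across replicates (eSD), and empirical 95%
#' coverage — plus an ELPD block per model. Replicate `r` uses seed
#' `base_seed + r`, so results are invariant to execution order.
#'
#' @param config A [sim_config()].
#' @param R Number of replicates.
#' @param models Character subset of `c("jmwiv", "constvar")`.
#' @param base_seed Integer base seed.
#' @param mcmc List of MCMC settings passed to [jmwiv()] (chains, warmup,
#'   sampling, adapt_delta, max_treedepth).
#' @param loo_reps Number of leading replicates on which to compute PSIS-LOO
#'   for each model (default 0).
#' @param progress Print per-replicate progress.
#' @return A list of class `"jm_simstudy"`: `table` (per model x parameter),
#'   `elpd` (per model x replicate), `intervals`, `estimates`, `failures`.
#' @export
run_simulation_study <- function(config = sim_config(), R = 20L,
                                 models = c("jmwiv", "constvar"),
                                 base_seed = 2026L,
                                 mcmc = list(chains = 1L, warmup = 300L,
                                             sampling = 300L,
                                             adapt_delta = 0.8,
                                             max_treedepth = 7L),
                                 loo_reps = 0L, progress = FALSE) {
  stopifnot(R >= 1L)
  models <- match.arg(models, several.ok = TRUE)
  truth <- sim_truth(config)
  est <- list(); ivl <- list(); elpd <- list()
  failures <- data.frame(replicate = integer(0), model = character(0),
                         message = character(0))
  for (r in seq_len(R)) {
    dat <- jm_simulate(config, seed = base_seed + r)
    for (model in models) {
      fit <- tryCatch(
        jmwiv(dat$long, dat$surv, association = "lp",
              constant_variance = (model == "constvar"),
              chains = mcmc$chains, warmup = mcmc$warmup,
              sampling = mcmc$sampling,
              adapt_delta = mcmc$adapt_delta %||% 0.8,
              max_treedepth = mcmc$max_treedepth %||% 7L,
              seed = base_seed + r, store_re = FALSE),
        error = function(e) e)
      if (inherits(fit, "error")) {
        failures <- rbind(failures,
                          data.frame(replicate = r, model = model,
                                     message = conditionMessage(fit)))
        next
      }
      s <- summarise_fit(fit)
      keep <- intersect(s$parameter, names(truth))
      srow <- s[match(keep, s$parameter), ]
      key <- paste(model, r, sep = ".")
      est[[key]] <- stats::setNames(srow$mean, keep)
      ivl[[key]] <- data.frame(model = model, replicate = r, parameter = keep,
                               lower = srow$q2.5, upper = srow$q97.5)
      if (r <= loo_reps) {
        lo <- compute_loo(fit)
        elpd[[key]] <- data.frame(model = model, replicate = r,
                                  elpd = lo$elpd, elpd_se = lo$elpd_se)
      }
      rm(fit)
      if (progress)
        message("replicate ", r, " / model ", model, " done")
    }
  }

  intervals <- do.call(rbind, ivl)
  rows <- list()
  for (model in models) {
    keys <- grep(paste0("^", model, "\\."), names(est), value = TRUE)
    if (!length(keys)) next
    pars <- names(est[[keys[1]]])
    M <- do.call(rbind, est[keys])
    for (p in pars) {
      iv <- intervals[intervals$model == model & intervals$parameter == p, ]
      rows[[paste(model, p)]] <- data.frame(
        model = model, parameter = p, truth = unname(truth[p]),
        mean = mean(M[, p]),
        esd = if (length(keys) > 1) stats::sd(M[, p]) else NA_real_,
        coverage = coverage(iv, truth[p]),
        n_reps = length(keys))
    }
  }
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 elpd = if (length(elpd)) do.call(rbind, elpd) else NULL,
                 estimates = est, intervals = intervals,
                 failures = failures, config = config, R = R,
                 base_seed = base_seed, mcmc = mcmc),
            class = "jm_simstudy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.jm_simstudy <- function(x, ...) {
  cat("Simulation study:", x$R, "replicates, N =", x$config$n_subjects, "\n")
  if (nrow(x$failures)) cat("  failed fits:", nrow(x$failures), "\n")
  print(x$table, digits = 3)
  if (!is.null(x$elpd)) {
    cat("\nELPD by model (mean over replicates):\n")
    print(stats::aggregate(elpd ~ model, data = x$elpd, FUN = mean), digits = 6)
  }
  invisible(x)
}
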