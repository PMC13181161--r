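#' Posterior summary table of a joint model fit
#'
#' One row per model parameter: posterior mean, MCMC standard error (the
#' posterior SD divided by the square root of the effective sample size),
#' posterior SD, 2.5% and 97.5% quantiles and the split R-hat statistic.
#' Association coefficients are additionally reported as hazard ratios
#' `exp(scale * alpha)` with exponentiated interval endpoints; `hr_scale`
#' rescales the unit (e.g. per-decilitre effects for a biomarker recorded in
#' litres).
#'
#' @param fit A [jmwiv()] fit.
#' @param hr_scale Multiplier applied to association coefficients before
#'   exponentiating (default 1).
#' @return A data frame with one row per parameter.
#' @export
summarise_fit <- function(fit, hr_scale = 1) {
  stopifnot(inherits(fit, "jmwiv_fit"))
  draws <- fit$draws
  qs <- t(apply(draws, 2, stats::quantile, probs = c(0.025, 0.975)))
  sds <- apply(draws, 2, stats::sd)
  ess <- fit$diagnostics$ess
  out <- data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    mcmc_se = sds / sqrt(pmax(ess, 1)),
    sd = sds,
    q2.5 = qs[, 1], q97.5 = qs[, 2],
    ess = ess,
    rhat = fit$diagnostics$rhat,
    row.names = NULL)
  degen <- sds < 1e-300
  out$mcmc_se[degen] <- 0
  out$rhat[degen] <- NA_real_
  is_alpha <- startsWith(out$parameter, "alpha_")
  out$hr <- ifelse(is_alpha, exp(hr_scale * out$mean), NA_real_)
  out$hr_q2.5 <- ifelse(is_alpha, exp(hr_scale * out$q2.5), NA_real_)
  out$hr_q97.5 <- ifelse(is_alpha, exp(hr_scale * out$q97.5), NA_real_)
  out
}
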