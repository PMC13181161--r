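# shared helpers to evaluate one posterior draw for one subject

draw_theta <- function(fit, j) {
  pidx <- fit$par_index
  u <- fit$all_unc[j, ]
  list(beta_mu = u[pidx$beta_mu],
       beta_sigma = u[pidx$beta_sig],
       gamma_w = u[pidx$gamma_w],
       alpha = u[pidx$alpha],
       gamma_h0 = u[pidx$gamma_h0])
}

subject_wgamma <- function(fit, i, theta) {
  wX <- stats::model.matrix(fit$meta$event_formula,
                            as.data.frame(fit$surv[i, , drop = FALSE]))
  wX <- wX[, colnames(wX) != "(Intercept)", drop = FALSE]
  if (!ncol(wX)) return(0)
  drop((wX - rep(fit$centers$w, each = nrow(wX))) %*% theta$gamma_w)
}

# eta_mu / eta_sigma (length(times) x K) for subject i under draw theta
subject_eta <- function(fit, i, times, theta, b_i) {
  designs <- fit$designs
  K <- designs$K
  off <- re_offsets(designs)
  pmu <- vapply(designs$mu, function(bl) ncol(bl$X), integer(1))
  psig <- vapply(designs$sigma, function(bl) ncol(bl$X), integer(1))
  omu <- cumsum(c(0, pmu)); osig <- cumsum(c(0, psig))
  em <- matrix(0, length(times), K); es <- matrix(0, length(times), K)
  for (k in seq_len(K)) {
    dm <- design_at(designs, "mu", k, rep(i, length(times)), times)
    ds <- design_at(designs, "sigma", k, rep(i, length(times)), times)
    em[, k] <- drop(dm$X %*% theta$beta_mu[(omu[k] + 1):omu[k + 1]])
    if (designs$L_mu[k] > 0)
      em[, k] <- em[, k] + drop(dm$Z %*% b_i[off$mu[k] + seq_len(designs$L_mu[k])])
    es[, k] <- drop(ds$X %*% theta$beta_sigma[(osig[k] + 1):osig[k + 1]])
    if (designs$L_sig[k] > 0)
      es[, k] <- es[, k] + drop(ds$Z %*% b_i[off$sigma[k] + seq_len(designs$L_sig[k])])
  }
  list(mu = em, sigma = es)
}

draw_hazard_fun <- function(fit, i, theta, b_i) {
  assoc <- fit$meta$association
  alpha_full <- numeric(length(fit$free_alpha))
  alpha_full[fit$free_alpha] <- theta$alpha
  wg <- subject_wgamma(fit, i, theta)
  designs <- fit$designs
  pmu <- vapply(designs$mu, function(bl) ncol(bl$X), integer(1))
  psig <- vapply(designs$sigma, function(bl) ncol(bl$X), integer(1))
  omu <- cumsum(c(0, pmu)); osig <- cumsum(c(0, psig))
  # per-biomarker centering offsets of the association predictors (matching
  # the centered parameterisation the model was fitted in)
  off_mu <- vapply(seq_len(designs$K), function(k)
    sum(fit$centers$assoc_mu[(omu[k] + 1):omu[k + 1]] *
          theta$beta_mu[(omu[k] + 1):omu[k + 1]]), numeric(1))
  off_sig <- vapply(seq_len(designs$K), function(k)
    sum(fit$centers$assoc_sigma[(osig[k] + 1):osig[k + 1]] *
          theta$beta_sigma[(osig[k] + 1):osig[k + 1]]), numeric(1))
  function(times) {
    ea <- if (assoc == "re")
      association_predictor("re", alpha_full, b = matrix(b_i, nrow = 1))
    else {
      e <- subject_eta(fit, i, times, theta, b_i)
      association_predictor(assoc, alpha_full,
                            sweep(e$mu, 2, off_mu),
                            sweep(e$sigma, 2, off_sig))
    }
    hazard_at(times, fit$spline, theta$gamma_h0, wg, ea)
  }
}

#' Posterior predicted survival curve for one subject
#'
#' For each posterior draw, \eqn{S_i(t) = \exp(-\int_{entry_i}^{t} h_i(s) ds)}
#' using the subject's drawn random effects, summarised pointwise by the
#' posterior mean and a credible band. `S(entry) = 1` by construction.
#'
#' @param fit A [jmwiv()] fit with `store_re = TRUE`.
#' @param id Subject identifier (as in the survival table).
#' @param times Time grid (within the baseline spline span); times before the
#'   subject's entry are not allowed.
#' @param draw_ids Optional subset of posterior draws (default: all).
#' @param level Credible level for the band (default 0.95).
#' @return List with `times`, per-draw matrix `S`, and `mean`, `lower`,
#'   `upper` summaries.
#' @export
predict_survival <- function(fit, id, times, draw_ids = NULL, level = 0.95) {
  stopifnot(inherits(fit, "jmwiv_fit"))
  if (is.null(fit$b_draws)) stop("fit was run with store_re = FALSE")
  i <- match(id, fit$designs$ids)
  if (is.na(i)) stop("unknown subject id")
  entry <- fit$surv$entry[i]
  if (any(times < entry)) stop("prediction times must not precede entry time")
  if (any(times > fit$spline$range[2] + 1e-8))
    stop("prediction grid extends beyond the baseline spline span")
  if (is.null(draw_ids)) draw_ids <- seq_len(nrow(fit$all_unc))
  S <- matrix(NA_real_, length(draw_ids), length(times))
  for (jj in seq_along(draw_ids)) {
    j <- draw_ids[jj]
    theta <- draw_theta(fit, j)
    hz <- draw_hazard_fun(fit, i, theta, fit$b_draws[j, i, ])
    S[jj, ] <- exp(-vapply(times, function(tt)
      cumulative_hazard(entry, max(tt, entry), hz, fit$rule), numeric(1)))
  }
  a <- (1 - level) / 2
  list(times = times, S = S, mean = colMeans(S),
       lower = apply(S, 2, stats::quantile, a),
       upper = apply(S, 2, stats::quantile, 1 - a))
}

#' Posterior predicted trajectory and within-individual variability band
#'
#' Summarises, per biomarker, the posterior of the subject's mean trajectory
#' \eqn{\eta_\mu(t)} and of the variability band
#' \eqn{\eta_\mu(t) \pm z \exp(\eta_\sigma(t))}.
#'
#' @inheritParams predict_survival
#' @param z Band half-width multiplier in residual SDs (default 1.96).
#' @return A list with one element per biomarker, each containing `times`,
#'   `mean` (posterior mean trajectory), `lower`/`upper` (posterior mean of
#'   the WIV band edges) and the per-draw matrices `eta_mu`, `eta_sigma`.
#' @export
predict_trajectory <- function(fit, id, times, z = 1.96, draw_ids = NULL) {
  stopifnot(inherits(fit, "jmwiv_fit"))
  if (is.null(fit$b_draws)) stop("fit was run with store_re = FALSE")
  i <- match(id, fit$designs$ids)
  if (is.na(i)) stop("unknown subject id")
  if (is.null(draw_ids)) draw_ids <- seq_len(nrow(fit$all_unc))
  K <- fit$designs$K
  em <- array(NA_real_, c(length(draw_ids), length(times), K))
  es <- array(NA_real_, c(length(draw_ids), length(times), K))
  for (jj in seq_along(draw_ids)) {
    j <- draw_ids[jj]
    theta <- draw_theta(fit, j)
    e <- subject_eta(fit, i, times, theta, fit$b_draws[j, i, ])
    em[jj, , ] <- e$mu; es[jj, , ] <- e$sigma
  }
  out <- vector("list", K)
  for (k in seq_len(K)) {
    mu_k <- em[, , k, drop = FALSE][, , 1, drop = TRUE]
    sg_k <- es[, , k, drop = FALSE][, , 1, drop = TRUE]
    mu_k <- matrix(mu_k, nrow = length(draw_ids))
    sg_k <- matrix(sg_k, nrow = length(draw_ids))
    out[[k]] <- list(times = times,
                     mean = colMeans(mu_k),
                     lower = colMeans(mu_k - z * exp(sg_k)),
                     upper = colMeans(mu_k + z * exp(sg_k)),
                     eta_mu = mu_k, eta_sigma = sg_k)
  }
  names(out) <- paste0("biomarker", seq_len(K))
  out
}
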