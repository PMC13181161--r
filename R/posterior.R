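#' Joint log posterior on the natural parameter scale
#'
#' Reference implementation of the unnormalised joint log posterior: the sum
#' of the event log-likelihoods, the longitudinal location-scale
#' log-likelihoods, the multivariate-normal density of the random effects
#' under \eqn{\Sigma = TPT}, and all log priors (including the Bayesian
#' P-spline prior on the baseline-hazard coefficients). Written for clarity,
#' not speed; model fitting uses the compiled equivalent. Out-of-support
#' parameters (non-positive \eqn{\tau}, invalid `corr`,
#' \eqn{\tau_h \notin (0,1)}) give `-Inf`.
#'
#' @param theta Named list with elements `beta_mu`, `beta_sigma` (fixed
#'   effects, concatenated over biomarkers), `gamma_w` (event covariate
#'   coefficients), `alpha` (association coefficients), `gamma_h0` (spline
#'   coefficients), `tau` (random-effect SDs), `corr` (correlation matrix) and
#'   `tau_h` (smoothing parameter).
#' @param b Random-effects matrix, subjects x components, block order
#'   \eqn{(\mu_1..\mu_K, \sigma_1..\sigma_K)}.
#' @param long,surv Validated data tables.
#' @param designs A [jm_designs()] object built from `long`.
#' @param spline A [bh_spline()] object.
#' @param association `"cv"`, `"lp"` or `"re"`.
#' @param priors A [jm_priors()] object.
#' @param rule A [gk_rule()] object.
#' @param event_formula RHS formula selecting event covariates from `surv`.
#' @param centers Optional list with `w`, `assoc_mu`, `assoc_sigma` centering
#'   constants of the event covariates and association design columns (the
#'   reparameterisation used by [jmwiv()]); `NULL` means no centering.
#' @return Scalar log posterior density (up to an additive constant).
#' @export
jm_log_posterior <- function(theta, b, long, surv, designs, spline,
                             association = c("cv", "lp", "re"),
                             priors = jm_priors(), rule = gk_rule(),
                             event_formula = ~ w1 + w2, centers = NULL) {
  association <- match.arg(association)
  K <- designs$K
  n_re <- designs$n_re
  if (any(!is.finite(theta$tau)) || any(theta$tau <= 0)) return(-Inf)
  if (!is.finite(theta$tau_h) || theta$tau_h <= 0 || theta$tau_h >= 1) return(-Inf)
  P <- as.matrix(theta$corr)
  if (max(abs(diag(P) - 1)) > 1e-8) return(-Inf)
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12) return(-Inf)
  Sigma <- assemble_covariance(theta$tau, P)

  surv <- surv[match(designs$ids, surv$id), , drop = FALSE]
  off <- re_offsets(designs)
  beta_of <- function(beta, lens) {
    o <- cumsum(c(0, lens))
    lapply(seq_along(lens), function(k) beta[(o[k] + 1):o[k + 1]])
  }
  pmu <- vapply(designs$mu, function(bl) ncol(bl$X), integer(1))
  psig <- vapply(designs$sigma, function(bl) ncol(bl$X), integer(1))
  bmu <- beta_of(theta$beta_mu, pmu)
  bsig <- beta_of(theta$beta_sigma, psig)

  # longitudinal contribution
  ll <- 0
  for (k in seq_len(K)) {
    blk_mu <- designs$mu[[k]]; blk_sig <- designs$sigma[[k]]
    b_mu <- b[, off$mu[k] + seq_len(designs$L_mu[k]), drop = FALSE]
    eta_mu <- linear_predictor(blk_mu, bmu[[k]], b_mu)
    if (designs$L_sig[k] > 0) {
      b_sig <- b[, off$sigma[k] + seq_len(designs$L_sig[k]), drop = FALSE]
      eta_sig <- linear_predictor(blk_sig, bsig[[k]], b_sig)
    } else {
      eta_sig <- drop(blk_sig$X %*% bsig[[k]])
    }
    ll <- ll + sum(longitudinal_loglik(long$value[blk_mu$rows], eta_mu, eta_sig))
  }

  # event contribution
  wX <- stats::model.matrix(event_formula, as.data.frame(surv))
  wX <- wX[, colnames(wX) != "(Intercept)", drop = FALSE]
  if (!is.null(centers) && length(centers$w)) wX <- sweep(wX, 2, centers$w)
  wgam <- if (ncol(wX)) drop(wX %*% theta$gamma_w) else numeric(designs$N)
  omu <- cumsum(c(0, pmu)); osig <- cumsum(c(0, psig))
  off_mu <- rep(0, K); off_sig <- rep(0, K)
  if (!is.null(centers)) {
    for (k in seq_len(K)) {
      if (length(centers$assoc_mu))
        off_mu[k] <- sum(centers$assoc_mu[(omu[k] + 1):omu[k + 1]] * bmu[[k]])
      if (length(centers$assoc_sigma))
        off_sig[k] <- sum(centers$assoc_sigma[(osig[k] + 1):osig[k + 1]] * bsig[[k]])
    }
  }
  eta_at <- function(i, times) {
    em <- matrix(0, length(times), K); es <- matrix(0, length(times), K)
    for (k in seq_len(K)) {
      dm <- design_at(designs, "mu", k, rep(i, length(times)), times)
      ds <- design_at(designs, "sigma", k, rep(i, length(times)), times)
      em[, k] <- drop(dm$X %*% bmu[[k]])
      if (designs$L_mu[k] > 0)
        em[, k] <- em[, k] + drop(dm$Z %*% b[i, off$mu[k] + seq_len(designs$L_mu[k])])
      es[, k] <- drop(ds$X %*% bsig[[k]])
      if (designs$L_sig[k] > 0)
        es[, k] <- es[, k] + drop(ds$Z %*% b[i, off$sigma[k] + seq_len(designs$L_sig[k])])
    }
    list(mu = em, sigma = es)
  }
  for (i in seq_len(designs$N)) {
    hz <- function(times) {
      ea <- if (association == "re")
        association_predictor("re", theta$alpha, b = matrix(b[i, ], nrow = 1))
      else {
        e <- eta_at(i, times)
        association_predictor(association, theta$alpha,
                              sweep(e$mu, 2, off_mu), sweep(e$sigma, 2, off_sig))
      }
      hazard_at(times, spline, theta$gamma_h0, wgam[i], ea)
    }
    ll <- ll + event_loglik(surv$entry[i], surv$time[i], surv$event[i], hz, rule)
  }

  # random effects density
  ll <- ll + sum(mvtnorm::dmvnorm(b, sigma = Sigma, log = TRUE))

  # priors
  lp <- sum(stats::dnorm(c(theta$beta_mu, theta$beta_sigma), 0, priors$beta_sd, log = TRUE)) +
    sum(stats::dnorm(theta$gamma_w, 0, priors$gamma_sd, log = TRUE)) +
    sum(stats::dnorm(theta$alpha, 0, priors$alpha_sd, log = TRUE)) +
    pspline_log_prior(theta$gamma_h0, theta$tau_h, spline) +
    sum(half_t_lpdf(theta$tau, priors$tau_df, priors$tau_scale)) +
    (priors$lkj_eta - 1) * determinant(P, logarithm = TRUE)$modulus +
    stats::dbeta(theta$tau_h, priors$tau_h_shape[1], priors$tau_h_shape[2], log = TRUE)

  as.numeric(ll + lp)
}
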