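#' Prior configuration for the joint model
#'
#' Defaults: normal(0, 10) for all fixed effects (longitudinal \eqn{\beta},
#' event \eqn{\gamma}, association \eqn{\alpha}); half-t(3, 2.5) for the
#' random-effect standard deviations \eqn{\tau}; LKJ(1) for the correlation
#' matrix `P`; Beta(1, 1) for the P-spline smoothing parameter
#' \eqn{\tau_h \in (0,1)}.
#'
#' @param beta_sd,gamma_sd,alpha_sd Normal prior SDs for the fixed-effect
#'   blocks.
#' @param tau_df,tau_scale Half-t prior degrees of freedom and scale for the
#'   random-effect SDs.
#' @param lkj_eta LKJ shape for the correlation matrix (1 = uniform over
#'   correlation matrices).
#' @param tau_h_shape Length-2 vector, Beta prior shapes for \eqn{\tau_h}.
#' @return A list of class `"jm_priors"`.
#' @export
jm_priors <- function(beta_sd = 10, gamma_sd = 10, alpha_sd = 10,
                      tau_df = 3, tau_scale = 2.5, lkj_eta = 1,
                      tau_h_shape = c(1, 1)) {
  stopifnot(beta_sd > 0, gamma_sd > 0, alpha_sd > 0, tau_df > 0,
            tau_scale > 0, lkj_eta > 0, all(tau_h_shape > 0))
  structure(list(beta_sd = beta_sd, gamma_sd = gamma_sd, alpha_sd = alpha_sd,
                 tau_df = tau_df, tau_scale = tau_scale, lkj_eta = lkj_eta,
                 tau_h_shape = tau_h_shape),
            class = "jm_priors")
}

# log density of the half-t distribution (x > 0), with normalizing constant
half_t_lpdf <- function(x, df, scale) {
  ifelse(x > 0,
         log(2) + stats::dt(x / scale, df, log = TRUE) - log(scale),
         -Inf)
}

# ---- C-vine canonical partial correlation (CPC) representation of LKJ ----
#
# For a d x d correlation matrix, the CPCs x_ij (1 <= i < j <= d, vine level
# i) are independent under LKJ(eta): (x_ij + 1)/2 ~ Beta(a_i, a_i) with
# a_i = eta + (d - 1 - i)/2. The sampler works on z = atanh(x).

# pair ordering used throughout: (1,2),(1,3),..,(1,d),(2,3),..,(d-1,d)
cpc_pairs <- function(d) {
  idx <- which(upper.tri(diag(d)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

cpc_beta_shapes <- function(d, eta = 1) {
  pairs <- cpc_pairs(d)
  eta + (d - 1 - pairs[, 1]) / 2
}

# partial-to-full correlation recursion (Joe 2006); x in pair order above
cpc_to_corr <- function(x, d) {
  pairs <- cpc_pairs(d)
  p <- matrix(0, d, d)
  p[pairs] <- x
  r <- diag(d)
  for (i in seq_len(d - 1)) {
    for (j in (i + 1):d) {
      rho <- p[i, j]
      if (i > 1) for (l in (i - 1):1)
        rho <- rho * sqrt((1 - p[l, i]^2) * (1 - p[l, j]^2)) + p[l, i] * p[l, j]
      r[i, j] <- r[j, i] <- rho
    }
  }
  r
}

# log prior of unconstrained z (x = tanh(z)) inducing LKJ(eta) on the matrix
lkj_cpc_log_prior <- function(z, d, eta = 1) {
  x <- tanh(z)
  a <- cpc_beta_shapes(d, eta)
  sum(stats::dbeta((x + 1) / 2, a, a, log = TRUE) - log(2) + log1p(-x^2))
}
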