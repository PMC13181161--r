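#' Build design matrices for the location-scale longitudinal submodel
#'
#' For each biomarker `k` and each submodel \eqn{\psi \in \{\mu, \sigma\}}
#' (mean and log residual SD) this builds the fixed-effect matrix
#' \eqn{X_{\psi k}} and random-effect matrix \eqn{Z_{\psi k}} from formulas,
#' so that \eqn{\eta_{i\psi k}(t) = X \beta_{\psi k} + Z b_{i\psi k}}.
#' The default is an intercept plus linear time in X and a random intercept
#' in Z for both submodels of every biomarker.
#'
#' Baseline covariates (anything other than the time variable) are centered by
#' default, so intercepts refer to the centered scale; disable with
#' `center = FALSE`. Covariates must be constant within subject except the
#' time variable.
#'
#' @param long A [jm_longitudinal()] table.
#' @param mu_fixed,sigma_fixed Fixed-effect formulas (RHS only), a single
#'   formula recycled over biomarkers or a list of length `K`.
#' @param mu_random,sigma_random Random-effect formulas, same conventions.
#' @param time_var Name of the time variable in the formulas (default
#'   `"time"`); it is never centered.
#' @param center Center non-time covariates (default `TRUE`).
#' @return An object of class `"jm_designs"`: per-(\eqn{\psi},k) design
#'   blocks, the subject table, and the random-effect layout
#'   (\eqn{\mu_1..\mu_K, \sigma_1..\sigma_K} block order).
#' @export
jm_designs <- function(long, mu_fixed = ~time, sigma_fixed = ~time,
                       mu_random = ~1, sigma_random = ~1,
                       time_var = "time", center = TRUE) {
  stopifnot(inherits(long, "jm_longitudinal"))
  K <- attr(long, "K")
  as_list <- function(f) if (inherits(f, "formula")) rep(list(f), K) else f
  mu_fixed <- as_list(mu_fixed); sigma_fixed <- as_list(sigma_fixed)
  mu_random <- as_list(mu_random); sigma_random <- as_list(sigma_random)
  for (f in list(mu_fixed, sigma_fixed, mu_random, sigma_random))
    if (length(f) != K) stop("need one formula, or a list of K formulas")

  ids <- sort(unique(long$id))
  N <- length(ids)
  subj_of_row <- match(long$id, ids)

  # subject-level covariate table: first row per subject, minus measurement cols
  first <- !duplicated(long$id)
  subjects <- as.data.frame(long)[first, setdiff(names(long),
                                                 c("time", "biomarker", "value")),
                                  drop = FALSE]
  subjects <- subjects[order(subjects$id), , drop = FALSE]
  rownames(subjects) <- NULL

  # centering constants, shared by the mu and sigma submodels
  vars <- unique(unlist(lapply(c(mu_fixed, sigma_fixed, mu_random, sigma_random),
                               all.vars)))
  unknown <- setdiff(vars, names(long))
  if (length(unknown)) stop("unknown covariate(s) in design formulas: ",
                            paste(unknown, collapse = ", "))
  centers <- numeric(0)
  if (center) {
    cand <- setdiff(vars, time_var)
    cand <- cand[vapply(cand, function(v) is.numeric(long[[v]]), logical(1))]
    centers <- vapply(cand, function(v) mean(long[[v]][first]), numeric(1))
  }

  make_block <- function(fixed, random, k, psi) {
    rows <- which(long$biomarker == k)
    dat <- as.data.frame(long)[rows, , drop = FALSE]
    for (v in names(centers)) dat[[v]] <- dat[[v]] - centers[[v]]
    X <- stats::model.matrix(fixed, dat)
    Z <- stats::model.matrix(random, dat)
    if (nrow(X) != length(rows) || nrow(Z) != length(rows))
      stop("design rows lost (missing covariate values?) for biomarker ", k)
    list(psi = psi, k = k, fixed = fixed, random = random,
         X = X, Z = Z, rows = rows, subj = subj_of_row[rows])
  }
  mu_blocks <- lapply(seq_len(K), function(k) make_block(mu_fixed[[k]], mu_random[[k]], k, "mu"))
  sig_blocks <- lapply(seq_len(K), function(k) make_block(sigma_fixed[[k]], sigma_random[[k]], k, "sigma"))

  L_mu <- vapply(mu_blocks, function(b) ncol(b$Z), integer(1))
  L_sig <- vapply(sig_blocks, function(b) ncol(b$Z), integer(1))
  structure(list(K = K, ids = ids, N = N, subjects = subjects,
                 mu = mu_blocks, sigma = sig_blocks,
                 L_mu = L_mu, L_sig = L_sig, n_re = sum(L_mu) + sum(L_sig),
                 time_var = time_var, centers = centers),
            class = "jm_designs")
}

# column offsets of each (psi, k) block inside the per-subject b vector,
# block order mu_1..mu_K, sigma_1..sigma_K
re_offsets <- function(designs) {
  L <- c(designs$L_mu, designs$L_sig)
  off <- cumsum(c(0L, L))[seq_along(L)]
  list(mu = off[seq_len(designs$K)],
       sigma = off[designs$K + seq_len(designs$K)])
}

# Rebuild the fixed/random design of one block for given subjects at given
# times (baseline covariates held at their subject values). Used when the
# association structure needs eta_psi_k at quadrature nodes or event times.
design_at <- function(designs, psi, k, subj_idx, times) {
  block <- designs[[psi]][[k]]
  dat <- designs$subjects[subj_idx, , drop = FALSE]
  for (v in names(designs$centers)) dat[[v]] <- dat[[v]] - designs$centers[[v]]
  dat[[designs$time_var]] <- times
  list(X = stats::model.matrix(block$fixed, dat),
       Z = stats::model.matrix(block$random, dat))
}

#' Linear predictor of one design block
#'
#' Computes \eqn{\eta = X\beta + Z b} per observation row, each row using its
#' own subject's random-effect subvector.
#'
#' @param block One design block from [jm_designs()] (e.g. `d$mu[[1]]`).
#' @param beta Fixed-effect vector, length `ncol(block$X)`.
#' @param b Random-effects matrix, subjects x `ncol(block$Z)` (a vector is
#'   accepted when there is a single random effect or a single subject).
#' @return Numeric vector of \eqn{\eta} values, one per row of the block.
#' @export
linear_predictor <- function(block, beta, b) {
  if (length(beta) != ncol(block$X)) stop("beta length does not match X")
  if (is.null(dim(b))) {
    b <- if (ncol(block$Z) == 1L) matrix(b, ncol = 1L) else matrix(b, nrow = 1L)
  }
  if (ncol(b) != ncol(block$Z)) stop("b width does not match Z")
  unname(drop(block$X %*% beta) +
           rowSums(block$Z * b[block$subj, , drop = FALSE]))
}

#' Assemble the random-effects covariance \eqn{\Sigma = T P T}
#'
#' @param tau Positive scale vector (diagonal of `T`), in the block order
#'   \eqn{\mu_1..\mu_K, \sigma_1..\sigma_K}.
#' @param corr Correlation matrix `P` (unit diagonal, positive definite).
#' @return Covariance matrix with `Sigma[a,b] = tau_a tau_b corr[a,b]`.
#' @export
assemble_covariance <- function(tau, corr) {
  if (any(!is.finite(tau)) || any(tau <= 0)) stop("tau must be strictly positive")
  corr <- as.matrix(corr)
  if (nrow(corr) != length(tau) || ncol(corr) != length(tau))
    stop("corr dimension does not match tau")
  if (max(abs(diag(corr) - 1)) > 1e-8 || max(abs(corr - t(corr))) > 1e-8)
    stop("corr must be symmetric with unit diagonal")
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("corr must be positive definite")
  diag(tau) %*% corr %*% diag(tau)
}

# inverse of assemble_covariance: recover (tau, corr) from Sigma
cov_to_scales <- function(Sigma) {
  tau <- sqrt(diag(Sigma))
  list(tau = tau, corr = Sigma / tcrossprod(tau))
}

#' Residual standard deviation from the scale linear predictor
#'
#' Applies the log link inverse, \eqn{\sigma = \exp(\eta_\sigma)}, with
#' overflow guarded.
#'
#' @param eta_sigma Linear predictor of the log residual SD.
#' @export
residual_sd <- function(eta_sigma) {
  exp(pmin(eta_sigma, 700))
}

#' Per-observation Gaussian log-likelihood with non-constant variance
#'
#' \deqn{\ell_{ijk} = -\tfrac12\log(2\pi) - \eta_\sigma -
#'   \tfrac12 (y - \eta_\mu)^2 e^{-2\eta_\sigma}}
#' Its sum over observations is the longitudinal contribution to the joint
#' log-likelihood.
#'
#' @param y Observed values.
#' @param eta_mu,eta_sigma Linear predictors of the mean and log residual SD.
#' @return Vector of per-observation log densities.
#' @export
longitudinal_loglik <- function(y, eta_mu, eta_sigma) {
  n <- length(y)
  if (length(eta_mu) != n || length(eta_sigma) != n)
    stop("y, eta_mu and eta_sigma must have equal length")
  -0.5 * log(2 * pi) - eta_sigma - 0.5 * (y - eta_mu)^2 * exp(-2 * eta_sigma)
}
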