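#' Association term linking the longitudinal process to the hazard
#'
#' Three structures are supported, all carrying information about the
#' within-individual variability:
#' \describe{
#'   \item{`"cv"` (current value)}{\eqn{\sum_k \alpha_{\mu k}\eta_{\mu k}(t) +
#'     \alpha_{\sigma k} \exp(\eta_{\sigma k}(t))} — the SD enters on its own
#'     scale.}
#'   \item{`"lp"` (linear predictor)}{\eqn{\sum_k \alpha_{\mu k}\eta_{\mu k}(t) +
#'     \alpha_{\sigma k} \eta_{\sigma k}(t)} — the log SD enters.}
#'   \item{`"re"` (random effects)}{\eqn{\alpha^\top b_i}, constant in time.}
#' }
#'
#' @param structure `"cv"`, `"lp"` or `"re"`.
#' @param alpha For `"cv"`/`"lp"`: vector `(alpha_mu_1..alpha_mu_K,
#'   alpha_sigma_1..alpha_sigma_K)`; `alpha_sigma` entries may be omitted
#'   (length `K`) for a mean-only association. For `"re"`: one coefficient per
#'   random-effect component.
#' @param eta_mu,eta_sigma Matrices (evaluation points x K) of the current
#'   mean and log-SD linear predictors; ignored for `"re"`.
#' @param b Per-subject random-effect vector (or matrix rows x components
#'   aligned with the evaluation points); required for `"re"`.
#' @return Vector of association terms \eqn{\eta_{i\alpha}}.
#' @export
association_predictor <- function(structure = c("cv", "lp", "re"), alpha,
                                  eta_mu = NULL, eta_sigma = NULL, b = NULL) {
  structure <- match.arg(structure)
  if (structure == "re") {
    if (is.null(b)) stop("association structure 're' needs random effects b")
    if (is.null(dim(b))) b <- matrix(b, nrow = 1L)
    if (length(alpha) != ncol(b)) stop("alpha length must match b components")
    return(drop(b %*% alpha))
  }
  eta_mu <- as.matrix(eta_mu); eta_sigma <- as.matrix(eta_sigma)
  K <- ncol(eta_mu)
  if (!length(alpha) %in% c(K, 2L * K))
    stop("alpha must have K or 2K components for cv/lp association")
  a_mu <- alpha[seq_len(K)]
  a_sig <- if (length(alpha) == 2L * K) alpha[K + seq_len(K)] else rep(0, K)
  sig_part <- if (structure == "cv") exp(eta_sigma) else eta_sigma
  drop(eta_mu %*% a_mu) + drop(sig_part %*% a_sig)
}

#' Hazard function under the proportional-hazards event submodel
#'
#' \deqn{h_i(t) = \exp(\log h_0(t) + w_i^\top\gamma + \eta_{i\alpha}(t))}
#' with the log baseline hazard expanded in the B-spline basis.
#'
#' @param times Evaluation times.
#' @param spline A [bh_spline()] object.
#' @param gamma_h0 Baseline-hazard spline coefficients.
#' @param wgamma Scalar \eqn{w_i^\top\gamma} for the subject (or vector
#'   aligned with `times`).
#' @param eta_alpha Association term at `times` (scalar or aligned vector);
#'   default 0.
#' @return Vector of positive hazard values.
#' @export
hazard_at <- function(times, spline, gamma_h0, wgamma = 0, eta_alpha = 0) {
  B <- bspline_basis(times, spline)
  exp(drop(B %*% gamma_h0) + wgamma + eta_alpha)
}

#' Cumulative hazard over a subject-specific interval by quadrature
#'
#' Approximates \eqn{\int_{entry}^{time} h(s)\,ds} with the quadrature rule
#' mapped affinely onto the interval (a single panel), which accounts for left
#' truncation by construction.
#'
#' @param entry,time Interval endpoints, `entry <= time`.
#' @param hazard A function of a time vector returning the hazard values.
#' @param rule A [gk_rule()] object.
#' @return Nonnegative scalar approximation of the integral.
#' @export
cumulative_hazard <- function(entry, time, hazard, rule = gk_rule()) {
  if (entry > time) stop("entry time exceeds observed time")
  if (entry == time) return(0)
  m <- map_rule(rule, entry, time)
  sum(m$weights * hazard(m$times))
}

#' Event log-likelihood of one survival record
#'
#' \deqn{\delta_i \log h_i(T_i) - \int_{entry_i}^{T_i} h_i(s)\,ds}
#'
#' @param entry,time,event Entry time, observed time and event indicator of
#'   the record.
#' @param hazard A function of a time vector returning the subject's hazard.
#' @param rule A [gk_rule()] object.
#' @export
event_loglik <- function(entry, time, event, hazard, rule = gk_rule()) {
  stopifnot(event %in% c(0, 1))
  ll <- -cumulative_hazard(entry, time, hazard, rule)
  if (event == 1) ll <- ll + log(hazard(time))
  ll
}
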