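#' Configuration for the Cox-Exponential JM-WIV simulator
#'
#' Generates joint data from a proportional-hazards model with constant
#' baseline hazard \eqn{\lambda} and a linear-predictor (LP) association with
#' a bivariate location-scale longitudinal model: intercept + linear time in
#' both the mean and the log-SD, with a random intercept for each
#' (\eqn{\psi}, k). The default values are the generating truth of the
#' package's recovery study.
#'
#' @param n_subjects Number of subjects `N`.
#' @param t_max Administrative horizon; censoring times are Uniform(0, t_max)
#'   and visits run every `visit_spacing` time units from 0.
#' @param lambda0 Constant baseline hazard \eqn{\lambda}.
#' @param w1_prob Success probability of the binary baseline covariate `w1`
#'   (`w2` is standard normal).
#' @param gamma Event-submodel baseline coefficients \eqn{(\gamma_1, \gamma_2)}.
#' @param alpha Association coefficients
#'   \eqn{(\alpha_{\mu 1}, \alpha_{\mu 2}, \alpha_{\sigma 1}, \alpha_{\sigma 2})}.
#' @param beta_mu,beta_sigma 2 x K matrices (intercept row, time-slope row) of
#'   fixed effects for the mean and log-SD submodels.
#' @param tau Random-intercept SDs \eqn{(\tau_{\mu 1}, \tau_{\mu 2},
#'   \tau_{\sigma 1}, \tau_{\sigma 2})}.
#' @param corr 4x4 random-effect correlation matrix in the same order.
#' @param visit_spacing Gap between scheduled visits (default 1).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_subjects = 1000L,
                       t_max = 10,
                       lambda0 = 10,
                       w1_prob = 0.5,
                       gamma = c(0.93, -2.3),
                       alpha = c(-2.24, 0.55, 1.9, 0.35),
                       beta_mu = cbind(c(2.19, -0.04), c(1.04, 0.35)),
                       beta_sigma = cbind(c(-1.36, -0.02), c(0.16, 0.01)),
                       tau = c(0.81, 0.52, 0.44, 0.16),
                       corr = default_sim_corr(),
                       visit_spacing = 1) {
  stopifnot(n_subjects >= 0, t_max > 0, lambda0 > 0,
            w1_prob >= 0, w1_prob <= 1, visit_spacing > 0,
            length(gamma) == 2, length(alpha) == 4,
            all(dim(beta_mu) == c(2, 2)), all(dim(beta_sigma) == c(2, 2)),
            length(tau) == 4, all(tau >= 0), all(dim(as.matrix(corr)) == c(4, 4)))
  structure(list(n_subjects = as.integer(n_subjects), t_max = t_max,
                 lambda0 = lambda0, w1_prob = w1_prob, gamma = gamma,
                 alpha = alpha, beta_mu = beta_mu, beta_sigma = beta_sigma,
                 tau = tau, corr = as.matrix(corr),
                 visit_spacing = visit_spacing),
            class = "sim_config")
}

#' Default random-effect correlation matrix of the simulator
#'
#' Positive correlation between the two biomarker means (0.5) and between the
#' mean and log-SD of each biomarker (0.4); all other pairs uncorrelated.
#' Order: \eqn{(\mu_1, \mu_2, \sigma_1, \sigma_2)}.
#' @export
default_sim_corr <- function() {
  P <- diag(4)
  P[1, 2] <- P[2, 1] <- 0.5   # mu1 - mu2
  P[1, 3] <- P[3, 1] <- 0.4   # mu1 - sigma1
  P[2, 4] <- P[4, 2] <- 0.4   # mu2 - sigma2
  P
}

#' Draw baseline covariates and random effects for each subject
#'
#' `w1` Bernoulli, `w2` standard normal, \eqn{b_i \sim N_4(0, TPT)}.
#'
#' @param config A [sim_config()].
#' @return List with matrix `w` (N x 2) and matrix `b` (N x 4).
#' @export
draw_subject_frame <- function(config) {
  N <- config$n_subjects
  w <- cbind(w1 = stats::rbinom(N, 1, config$w1_prob),
             w2 = stats::rnorm(N))
  Sigma <- diag(config$tau) %*% config$corr %*% diag(config$tau)
  b <- if (N > 0) mvtnorm::rmvnorm(N, sigma = Sigma) else matrix(0, 0, 4)
  colnames(b) <- c("b_mu1", "b_mu2", "b_sig1", "b_sig2")
  list(w = w, b = b)
}

#' Per-subject log-hazard intercept and slope under the LP association
#'
#' Substituting the intercept + slope location-scale predictors into the LP
#' association collapses the hazard to
#' \eqn{h_i(t) = \exp(\log\lambda + w_i^\top\gamma + A_i + B t)} with
#' \deqn{A_i = \sum_k \alpha_{\mu k}(\beta_{0\mu k} + b_{i\mu k}) +
#'             \alpha_{\sigma k}(\beta_{0\sigma k} + b_{i\sigma k}),\quad
#'       B = \sum_k \alpha_{\mu k}\beta_{1\mu k} +
#'             \alpha_{\sigma k}\beta_{1\sigma k}.}
#'
#' @param config A [sim_config()].
#' @param b Length-4 random-effect vector \eqn{(b_{\mu1}, b_{\mu2},
#'   b_{\sigma1}, b_{\sigma2})} (or N x 4 matrix).
#' @return List with `A` (per subject) and scalar `B`.
#' @export
linear_hazard_terms <- function(config, b) {
  if (is.null(dim(b))) b <- matrix(b, nrow = 1L)
  a_mu <- config$alpha[1:2]; a_sig <- config$alpha[3:4]
  A <- drop((sweep(b[, 1:2, drop = FALSE], 2, config$beta_mu[1, ], "+") %*% a_mu) +
            (sweep(b[, 3:4, drop = FALSE], 2, config$beta_sigma[1, ], "+") %*% a_sig))
  B <- sum(a_mu * config$beta_mu[2, ]) + sum(a_sig * config$beta_sigma[2, ])
  list(A = A, B = B)
}

#' Invert the cumulative hazard to generate an event time
#'
#' Solves \eqn{\int_0^T \lambda e^{w^\top\gamma + A + Bs} ds = -\log u}:
#' \deqn{T = \frac{1}{B}\log\left(1 - \frac{B \log u}
#'   {\lambda e^{w^\top\gamma + A}}\right)}
#' with the exponential limit \eqn{-\log u / (\lambda e^{w^\top\gamma + A})}
#' when `B = 0`. When `B < 0` the cumulative hazard plateaus; if the plateau
#' is below \eqn{-\log u} the event never occurs and `Inf` is returned.
#'
#' @param u Uniform(0,1] draw(s).
#' @param config A [sim_config()].
#' @param A,B Subject log-hazard intercept and common slope from
#'   [linear_hazard_terms()].
#' @param wgamma \eqn{w_i^\top \gamma} value(s).
#' @return Event time(s) in \eqn{[0, \infty]}.
#' @export
invert_event_time <- function(u, config, A, B, wgamma) {
  stopifnot(all(u > 0), all(u <= 1))
  c0 <- config$lambda0 * exp(wgamma + A)
  if (abs(B) < 1e-12) return(-log(u) / c0)
  arg <- 1 - B * log(u) / c0
  ifelse(arg > 0, log(arg) / B, Inf)
}

#' Apply independent uniform censoring
#'
#' Censoring times are Uniform(0, t_max); the observed time is the minimum of
#' event and censoring time and the event indicator flags which came first.
#'
#' @param T_event Event time(s), possibly `Inf`.
#' @param config A [sim_config()].
#' @param T_cens Optional censoring times (drawn internally by default).
#' @return List with `time` (observed) and `event` (0/1).
#' @export
apply_censoring <- function(T_event, config, T_cens = NULL) {
  if (is.null(T_cens))
    T_cens <- stats::runif(length(T_event), 0, config$t_max)
  event <- as.integer(T_event <= T_cens)
  list(time = pmin(T_event, T_cens), event = event)
}

#' Generate the longitudinal measurements of one subject
#'
#' Visits at 0, spacing, 2*spacing, ... up to the observed time (every
#' subject has at least the baseline visit), with
#' \eqn{y_{ijk} \sim N(\eta_{\mu k}(t_{ij}), \exp(\eta_{\sigma k}(t_{ij}))^2)}
#' under the intercept + slope location-scale predictors.
#'
#' @param id Subject identifier.
#' @param observed_time The subject's observed event/censoring time.
#' @param config A [sim_config()].
#' @param b Length-4 random-effect vector.
#' @return Data frame rows `(id, time, biomarker, value)`.
#' @export
generate_longitudinal <- function(id, observed_time, config, b) {
  times <- seq(0, max(observed_time, 0), by = config$visit_spacing)
  K <- 2L
  out <- vector("list", K)
  for (k in seq_len(K)) {
    eta_mu <- config$beta_mu[1, k] + b[k] + config$beta_mu[2, k] * times
    eta_sig <- config$beta_sigma[1, k] + b[2 + k] + config$beta_sigma[2, k] * times
    out[[k]] <- data.frame(id = id, time = times, biomarker = k,
                           value = stats::rnorm(length(times), eta_mu,
                                                exp(eta_sig)))
  }
  do.call(rbind, out)
}

#' Simulate a joint dataset from the Cox-Exponential JM-WIV model
#'
#' Runs the full generator: covariates and random effects, closed-form event
#' times, uniform censoring, and the regular-schedule location-scale
#' longitudinal process. All subjects enter at time 0.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed (set once for the whole dataset).
#' @return List with `long` ([jm_longitudinal()]), `surv` ([jm_survival()]
#'   with covariate columns `w1`, `w2`) and `truth` (every generating
#'   parameter plus the per-subject `b`, `u`, `A`, `B` and latent event time).
#' @export
jm_simulate <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- config$n_subjects
  if (N == 0L) {
    return(list(long = NULL, surv = NULL,
                truth = list(config = config, b = matrix(0, 0, 4))))
  }
  frame <- draw_subject_frame(config)
  hz <- linear_hazard_terms(config, frame$b)
  wgamma <- drop(frame$w %*% config$gamma)
  u <- stats::runif(N)
  T_event <- invert_event_time(u, config, hz$A, hz$B, wgamma)
  cens <- apply_censoring(T_event, config)
  long <- do.call(rbind, lapply(seq_len(N), function(i)
    generate_longitudinal(i, cens$time[i], config, frame$b[i, ])))
  surv <- data.frame(id = seq_len(N), entry = 0, time = cens$time,
                     event = cens$event, w1 = frame$w[, 1], w2 = frame$w[, 2])
  list(long = jm_longitudinal(long),
       surv = jm_survival(surv),
       truth = list(config = config, b = frame$b, w = frame$w, u = u,
                    A = hz$A, B = hz$B, wgamma = wgamma,
                    event_time = T_event))
}
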