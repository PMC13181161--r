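# Generalized Pareto fit to sample exceedances (profile-posterior method of
# Zhang & Stephens 2009). Returns the EVT tail shape xi (positive = heavy).
gpd_fit <- function(x, prior_bs = 3, wip = TRUE) {
  x <- sort(x[x > 0])
  n <- length(x)
  if (n < 5) return(list(xi = NA_real_, sigma = NA_real_))
  m <- 30L + floor(sqrt(n))
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  b <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (prior_bs * xstar)
  prof <- vapply(b, function(bi) {
    k <- -mean(log1p(-bi * x))
    n * (log(bi / k) + k - 1)
  }, numeric(1))
  w <- exp(prof - max(prof)); w <- w / sum(w)
  bhat <- sum(b * w)
  khat <- -mean(log1p(-bhat * x))
  sigma <- khat / bhat
  xi <- -khat
  if (wip) xi <- (xi * n + 0.5 * 10) / (n + 10)   # weak shrinkage to 0.5
  list(xi = xi, sigma = sigma, khat_zs = khat, bhat = bhat)
}

# quantile of the Zhang-Stephens-parameterised GPD
gpd_quantile <- function(p, khat_zs, sigma) {
  if (abs(khat_zs) < 1e-12) return(-sigma * log1p(-p))
  (sigma / khat_zs) * (1 - (1 - p)^khat_zs)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Pareto-smoothed importance sampling of one log-weight vector.
# Returns smoothed log weights (normalised to max 0) and the tail shape.
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5 || S < 25) return(list(lw = lw, pareto_k = NA_real_))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cut <- exp(lw[ord[S - M]])
  exc <- exp(lw[tail_ids]) - cut
  fitp <- gpd_fit(exc)
  if (!is.finite(fitp$xi)) return(list(lw = lw, pareto_k = NA_real_))
  p <- (seq_len(M) - 0.5) / M
  smoothed <- log(vapply(p, gpd_quantile, numeric(1),
                         khat_zs = fitp$khat_zs, sigma = fitp$sigma) + cut)
  lw[tail_ids[order(lw[tail_ids])]] <- pmin(smoothed, 0)
  list(lw = lw - max(lw), pareto_k = fitp$xi)
}

#' PSIS-LOO expected log predictive density of a fit
#'
#' Approximate leave-one-subject-out cross-validation from the posterior
#' draws: for each subject the importance ratios are the reciprocals of that
#' subject's likelihood contributions, their upper tail is smoothed by a
#' generalized-Pareto fit (PSIS), and the expected log predictive density
#' (ELPD) is the weighted predictive density summed over subjects. The
#' per-subject likelihood is conditional on the subject's drawn random
#' effects (the longitudinal terms plus the event term).
#'
#' @param fit A [jmwiv()] fit (its `pointwise_loglik` is used).
#' @return A list of class `"jm_loo"`: `elpd`, `elpd_se`, per-subject
#'   `pointwise` and `pareto_k` diagnostics.
#' @export
compute_loo <- function(fit) {
  ll <- if (inherits(fit, "jmwiv_fit")) fit$pointwise_loglik else as.matrix(fit)
  S <- nrow(ll); N <- ncol(ll)
  if (S < 25) stop("too few posterior draws for PSIS tail fitting")
  elpd_i <- numeric(N); k_i <- numeric(N)
  for (i in seq_len(N)) {
    sm <- psis_smooth(-ll[, i])
    elpd_i[i] <- logsumexp(sm$lw + ll[, i]) - logsumexp(sm$lw)
    k_i[i] <- sm$pareto_k
  }
  structure(list(elpd = sum(elpd_i),
                 elpd_se = sqrt(N * stats::var(elpd_i)),
                 pointwise = elpd_i, pareto_k = k_i),
            class = "jm_loo")
}

#' @export
print.jm_loo <- function(x, ...) {
  cat("PSIS-LOO: elpd =", round(x$elpd, 2), "(se", round(x$elpd_se, 2), ")\n")
  nk <- sum(is.finite(x$pareto_k) & x$pareto_k > 0.7)
  if (nk) cat("  ", nk, "subject(s) with Pareto k > 0.7\n")
  invisible(x)
}

#' Compare two fits by their ELPD difference
#'
#' @param loo1,loo2 Results of [compute_loo()] on the same data.
#' @return List with the ELPD difference (`loo1 - loo2`) and its standard
#'   error computed from the paired per-subject differences.
#' @export
loo_difference <- function(loo1, loo2) {
  d <- loo1$pointwise - loo2$pointwise
  list(elpd_diff = sum(d), se_diff = sqrt(length(d) * stats::var(d)))
}
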