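#' Penalized B-spline specification for the log baseline hazard
#'
#' The log baseline hazard is expanded in `L` B-spline basis functions over
#' the observed time range, \eqn{\log h_0(t) = \sum_l \gamma_{h0,l} B_l(t)},
#' with an r-th order difference penalty on adjacent coefficients (a P-spline).
#' Knots are equally spaced over `range` with coincident boundary knots, so
#' the basis is a partition of unity on the whole span.
#'
#' @param range Numeric length-2: time span covered by the spline, typically
#'   `c(0, max(observed_time))`.
#' @param L Number of basis functions (default 6).
#' @param degree Spline degree (default 3, cubic).
#' @param diff_order Order `r` of the difference penalty (default 2).
#' @return Object of class `"jm_bspline"` with the knot vector, dimensions and
#'   the penalty rank `pen_rank = L - diff_order`.
#' @export
bh_spline <- function(range, L = 6L, degree = 3L, diff_order = 2L) {
  stopifnot(length(range) == 2, is.finite(range), range[2] > range[1])
  L <- as.integer(L); degree <- as.integer(degree); diff_order <- as.integer(diff_order)
  if (L < degree + 1L) stop("need L >= degree + 1 basis functions")
  if (diff_order >= L) stop("difference order must be smaller than L")
  n_inner <- L - degree - 1L            # interior knots
  ord <- degree + 1L
  inner <- if (n_inner > 0)
    seq(range[1], range[2], length.out = n_inner + 2L)[-c(1L, n_inner + 2L)]
  else numeric(0)
  knots <- c(rep(range[1], ord), inner, rep(range[2], ord))
  structure(list(range = range, L = L, degree = degree, knots = knots,
                 diff_order = diff_order, pen_rank = L - diff_order),
            class = "jm_bspline")
}

#' Evaluate the B-spline basis
#'
#' Times outside the knot span are clamped to the boundaries, so the basis
#' (and hence the baseline hazard) is extended as constant beyond the range.
#'
#' @param times Numeric vector of evaluation times.
#' @param spline A [bh_spline()] object.
#' @return Matrix `length(times) x L`; rows sum to 1.
#' @export
bspline_basis <- function(times, spline) {
  stopifnot(inherits(spline, "jm_bspline"))
  t_cl <- pmin(pmax(times, spline$range[1]), spline$range[2])
  B <- splines::splineDesign(spline$knots, t_cl, ord = spline$degree + 1L,
                             outer.ok = FALSE)
  dimnames(B) <- NULL
  B
}

# r-th order difference matrix ((L - r) x L), rows are the stencils of Delta_r.
diff_matrix <- function(L, r) {
  D <- diag(L)
  for (i in seq_len(r)) D <- diff(D)
  D
}

#' Log density of the Bayesian P-spline prior (up to an additive constant)
#'
#' \deqn{\log p(\gamma | \tau_h) = (\rho/2)\log\tau_h -
#'   (\tau_h/2)\, \gamma^\top \Delta_r^\top \Delta_r \gamma + c}
#' where \eqn{\rho = L - r} is the rank of the penalty. The prior is partially
#' improper: polynomial trends of degree `< r` in the coefficient index are
#' unpenalized.
#'
#' @param gamma_h0 Spline coefficient vector (length `L`).
#' @param tau_h Smoothing parameter, in \eqn{(0, 1)} under the model's Beta
#'   prior (must be positive here).
#' @param spline A [bh_spline()] object.
#' @export
pspline_log_prior <- function(gamma_h0, tau_h, spline) {
  stopifnot(inherits(spline, "jm_bspline"), length(gamma_h0) == spline$L)
  if (!is.finite(tau_h) || tau_h <= 0) stop("tau_h must be positive")
  D <- diff_matrix(spline$L, spline$diff_order)
  pen <- sum((D %*% gamma_h0)^2)
  (spline$pen_rank / 2) * log(tau_h) - (tau_h / 2) * pen
}
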