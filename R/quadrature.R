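# 15-point Gauss-Kronrod rule on [-1, 1] (QUADPACK K15 abscissae/weights).
.gk15_nodes <- c(
  -0.991455371120813, -0.949107912342759, -0.864864423359769,
  -0.741531185599394, -0.586087235467691, -0.405845151377397,
  -0.207784955007898,  0.000000000000000,  0.207784955007898,
   0.405845151377397,  0.586087235467691,  0.741531185599394,
   0.864864423359769,  0.949107912342759,  0.991455371120813)

.gk15_weights <- c(
  0.022935322010529, 0.063092092629979, 0.104790010322250,
  0.140653259715525, 0.169004726639267, 0.190350578064785,
  0.204432940075298, 0.209482141084728, 0.204432940075298,
  0.190350578064785, 0.169004726639267, 0.140653259715525,
  0.104790010322250, 0.063092092629979, 0.022935322010529)

#' Quadrature rule for the cumulative hazard
#'
#' Returns a fixed quadrature rule on \eqn{[-1, 1]} used to approximate the
#' cumulative hazard over a subject-specific interval. `Q = 15` (the default
#' throughout the package) gives the 15-point Gauss--Kronrod rule; any other
#' `Q >= 7` falls back to a Gauss--Legendre rule of that order.
#'
#' @param Q Integer number of nodes (>= 7). Default 15.
#' @return A list of class `"jm_quadrature"` with elements `Q`, `nodes`
#'   (in \eqn{(-1,1)}) and `weights` (positive, summing to 2).
#' @examples
#' r <- gk_rule()
#' sum(r$weights)  # 2
#' @export
gk_rule <- function(Q = 15L) {
  Q <- as.integer(Q)
  if (Q < 7L) stop("quadrature rule needs Q >= 7 nodes")
  if (Q == 15L) {
    rule <- list(Q = Q, nodes = .gk15_nodes, weights = .gk15_weights)
  } else {
    gl <- statmod::gauss.quad(Q, kind = "legendre")
    rule <- list(Q = Q, nodes = gl$nodes, weights = gl$weights)
  }
  class(rule) <- "jm_quadrature"
  rule
}

# Map a rule on [-1,1] to [a, b]; returns node locations and scaled weights.
map_rule <- function(rule, a, b) {
  half <- (b - a) / 2
  list(times = (a + b) / 2 + half * rule$nodes,
       weights = half * rule$weights)
}
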