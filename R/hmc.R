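# No-U-Turn sampler (multinomial variant) on an arbitrary differentiable
# log density, with dual-averaging step-size adaptation and windowed
# estimation of the mass matrix during warmup. The metric is diagonal except
# on an optional `dense_idx` block (here: the model parameters, whose strong
# posterior correlations would otherwise force very long trajectories; the
# per-subject innovations keep a diagonal metric). `fn`/`gr` follow the TMB
# convention (negative log posterior and its gradient).

# metric object: estimated posterior covariance, diagonal + one dense block
make_metric <- function(d, dense_idx = integer(0), diag_var = rep(1, d),
                        dense_cov = NULL) {
  m <- list(diag = diag_var, idx = dense_idx)
  if (length(dense_idx)) {
    if (is.null(dense_cov)) dense_cov <- diag(diag_var[dense_idx],
                                              length(dense_idx))
    m$R <- chol(dense_cov)              # upper triangular, cov = R'R
  }
  m
}

# velocity = (estimated covariance) %*% momentum
metric_vel <- function(m, p) {
  v <- m$diag * p
  if (length(m$idx)) v[m$idx] <- drop(crossprod(m$R, m$R %*% p[m$idx]))
  v
}

# momentum ~ N(0, inverse covariance)
metric_momentum <- function(m) {
  z <- stats::rnorm(length(m$diag))
  p <- z / sqrt(m$diag)
  if (length(m$idx)) p[m$idx] <- backsolve(m$R, z[m$idx])
  p
}

metric_kinetic <- function(m, p) 0.5 * sum(p * metric_vel(m, p))

nuts_sample <- function(fn, gr, init,
                        n_warmup = 1000L, n_sample = 1000L,
                        adapt_delta = 0.8, max_treedepth = 10L,
                        dense_idx = integer(0), progress = FALSE) {
  d <- length(init)
  lp <- function(x) {
    v <- -fn(x)
    if (!is.finite(v)) -Inf else v
  }
  glp <- function(x) -gr(x)

  metric <- make_metric(d, dense_idx)
  theta <- init
  logp <- lp(theta)
  if (!is.finite(logp)) stop("initial point has zero posterior density")
  grad <- glp(theta)

  eps <- find_step(lp, glp, theta, metric)

  # dual averaging state
  da_reset <- function(e) list(mu = log(10 * e), log_eps_bar = 0, H = 0, m = 0)
  da <- da_reset(eps)
  gamma0 <- 0.05; t0 <- 10; kappa <- 0.75

  # mass-adaptation windows (step-only buffers around expanding cov windows)
  init_buf <- min(max(25L, floor(0.15 * n_warmup)), n_warmup)
  term_buf <- min(max(25L, floor(0.10 * n_warmup)), n_warmup)
  wins <- integer(0)
  if (n_warmup > init_buf + term_buf + 20L) {
    lo <- init_buf; size <- 25L
    while (lo + size < n_warmup - term_buf) {
      nxt <- lo + size
      if (nxt + 2L * size >= n_warmup - term_buf) nxt <- n_warmup - term_buf
      wins <- c(wins, nxt); lo <- nxt; size <- size * 2L
    }
  }
  acc_n <- 0L; acc_mean <- NULL; acc_m2 <- NULL; acc_block <- NULL

  n_total <- n_warmup + n_sample
  draws <- matrix(NA_real_, n_sample, d)
  stats <- data.frame(accept_stat = numeric(n_sample), treedepth = integer(n_sample),
                      n_leapfrog = integer(n_sample), divergent = integer(n_sample),
                      energy = numeric(n_sample))
  div_warm <- 0L

  for (it in seq_len(n_total)) {
    r <- nuts_transition(theta, logp, grad, eps, metric, lp, glp,
                         max_treedepth)
    theta <- r$theta; logp <- r$logp; grad <- r$grad

    if (it <= n_warmup) {
      if (r$divergent) div_warm <- div_warm + 1L
      # dual averaging towards the target acceptance statistic
      da$m <- da$m + 1
      da$H <- (1 - 1 / (da$m + t0)) * da$H + (adapt_delta - r$accept_stat) / (da$m + t0)
      log_eps <- da$mu - sqrt(da$m) / gamma0 * da$H
      w <- da$m^(-kappa)
      da$log_eps_bar <- w * log_eps + (1 - w) * da$log_eps_bar
      eps <- exp(log_eps)
      # accumulate moments inside the current window
      if (it > init_buf && it <= n_warmup - term_buf) {
        acc_n <- acc_n + 1L
        if (acc_n == 1L) {
          acc_mean <- theta; acc_m2 <- numeric(d)
          acc_block <- matrix(0, length(dense_idx), length(dense_idx))
        } else {
          dlt <- theta - acc_mean
          acc_mean <- acc_mean + dlt / acc_n
          dlt2 <- theta - acc_mean
          acc_m2 <- acc_m2 + dlt * dlt2
          if (length(dense_idx))
            acc_block <- acc_block + tcrossprod(dlt[dense_idx], dlt2[dense_idx])
        }
      }
      if (it %in% wins && acc_n > 4L) {
        v <- acc_m2 / (acc_n - 1)
        dv <- v * acc_n / (acc_n + 5) + 1e-3 * 5 / (acc_n + 5)
        dcov <- NULL
        if (length(dense_idx)) {
          S <- acc_block / (acc_n - 1)
          dcov <- S * acc_n / (acc_n + 5) +
            diag(1e-3 * 5 / (acc_n + 5), length(dense_idx))
        }
        metric <- make_metric(d, dense_idx, dv, dcov)
        acc_n <- 0L
        eps <- find_step(lp, glp, theta, metric)
        da <- da_reset(eps)
      }
      if (it == n_warmup) eps <- exp(da$log_eps_bar)
    } else {
      j <- it - n_warmup
      draws[j, ] <- theta
      stats$accept_stat[j] <- r$accept_stat
      stats$treedepth[j] <- r$depth
      stats$n_leapfrog[j] <- r$n_lf
      stats$divergent[j] <- as.integer(r$divergent)
      stats$energy[j] <- -logp
    }
    if (progress && it %% 100L == 0L)
      message("iteration ", it, "/", n_total, " (eps = ", signif(eps, 3), ")")
  }
  list(draws = draws, stats = stats, step_size = eps, metric = metric,
       divergent_warmup = div_warm)
}

# one NUTS transition (multinomial sampling across the trajectory)
nuts_transition <- function(theta, logp, grad, eps, metric, lp, glp,
                            max_treedepth) {
  p0 <- metric_momentum(metric)
  H0 <- logp - metric_kinetic(metric, p0)

  leapfrog <- function(th, p, g, dir) {
    e <- dir * eps
    p1 <- p + 0.5 * e * g
    th1 <- th + e * metric_vel(metric, p1)
    lp1 <- lp(th1)
    g1 <- if (is.finite(lp1)) glp(th1) else rep(0, length(th))
    p1 <- p1 + 0.5 * e * g1
    list(theta = th1, p = p1, logp = lp1, grad = g1,
         H = if (is.finite(lp1)) lp1 - metric_kinetic(metric, p1) else -Inf)
  }

  build <- function(st, dir, depth) {
    if (depth == 0L) {
      s <- leapfrog(st$theta, st$p, st$grad, dir)
      dh <- s$H - H0
      div <- !is.finite(dh) || dh < -1000
      list(minus = s, plus = s, prop = s, logw = dh,
           sum_acc = if (is.finite(dh)) min(1, exp(min(dh, 0))) else 0,
           n_lf = 1L, divergent = div, ok = !div)
    } else {
      t1 <- build(st, dir, depth - 1L)
      if (!t1$ok) return(t1)
      st2 <- if (dir == 1) t1$plus else t1$minus
      t2 <- build(st2, dir, depth - 1L)
      out <- list(minus = if (dir == 1) t1$minus else t2$minus,
                  plus = if (dir == 1) t1$plus else t2$plus,
                  n_lf = t1$n_lf + t2$n_lf,
                  sum_acc = t1$sum_acc + t2$sum_acc,
                  divergent = t1$divergent || t2$divergent)
      if (!t2$ok) { out$ok <- FALSE; out$prop <- t1$prop; out$logw <- t1$logw; return(out) }
      tot <- logsum2(t1$logw, t2$logw)
      out$prop <- if (log(stats::runif(1)) < t2$logw - tot) t2$prop else t1$prop
      out$logw <- tot
      out$ok <- !uturn(out$minus, out$plus, metric)
      out
    }
  }

  st0 <- list(theta = theta, p = p0, logp = logp, grad = grad, H = H0)
  tree <- list(minus = st0, plus = st0, prop = st0, logw = 0,
               sum_acc = 0, n_lf = 0L, divergent = FALSE, ok = TRUE)
  depth <- 0L
  while (depth < max_treedepth && tree$ok) {
    dir <- if (stats::runif(1) < 0.5) -1 else 1
    st <- if (dir == 1) tree$plus else tree$minus
    sub <- build(st, dir, depth)
    nt <- list(minus = if (dir == 1) tree$minus else sub$minus,
               plus = if (dir == 1) tree$plus else sub$plus,
               n_lf = tree$n_lf + sub$n_lf,
               sum_acc = tree$sum_acc + sub$sum_acc,
               divergent = tree$divergent || sub$divergent)
    if (sub$ok) {
      tot <- logsum2(tree$logw, sub$logw)
      nt$prop <- if (log(stats::runif(1)) < sub$logw - tot) sub$prop else tree$prop
      nt$logw <- tot
      nt$ok <- !uturn(nt$minus, nt$plus, metric)
    } else {
      nt$prop <- tree$prop; nt$logw <- tree$logw; nt$ok <- FALSE
    }
    tree <- nt
    depth <- depth + 1L
    if (!sub$ok) break
  }
  pr <- tree$prop
  list(theta = pr$theta, logp = pr$logp, grad = pr$grad,
       accept_stat = if (tree$n_lf > 0) tree$sum_acc / tree$n_lf else 0,
       depth = depth, n_lf = tree$n_lf, divergent = tree$divergent)
}

logsum2 <- function(a, b) {
  m <- max(a, b)
  if (!is.finite(m)) return(-Inf)
  m + log(exp(a - m) + exp(b - m))
}

# generalized U-turn criterion on the endpoints, in velocity coordinates
uturn <- function(minus, plus, metric) {
  dth <- plus$theta - minus$theta
  sum(dth * metric_vel(metric, minus$p)) < 0 ||
    sum(dth * metric_vel(metric, plus$p)) < 0
}

# crude initial step size: double/halve until the one-step acceptance
# probability crosses 1/2 (Hoffman-Gelman heuristic)
find_step <- function(lp, glp, theta, metric, eps = 0.1) {
  p <- metric_momentum(metric)
  H0 <- lp(theta) - metric_kinetic(metric, p)
  one <- function(e) {
    p1 <- p + 0.5 * e * glp(theta)
    th1 <- theta + e * metric_vel(metric, p1)
    l1 <- lp(th1)
    if (!is.finite(l1)) return(-Inf)
    p1 <- p1 + 0.5 * e * glp(th1)
    l1 - metric_kinetic(metric, p1) - H0
  }
  dh <- one(eps)
  dir <- if (is.finite(dh) && dh > log(0.5)) 1 else -1
  for (i in 1:50) {
    eps2 <- eps * 2^dir
    dh <- one(eps2)
    ok <- is.finite(dh) && dh > log(0.5)
    if ((dir == 1 && !ok) || (dir == -1 && ok)) break
    eps <- eps2
  }
  eps
}

# split-R-hat over a list of per-chain draw matrices (iterations x params)
split_rhat <- function(mat_list) {
  halves <- list()
  for (m in mat_list) {
    n <- nrow(m); h <- floor(n / 2)
    halves <- c(halves, list(m[seq_len(h), , drop = FALSE],
                             m[(n - h + 1):n, , drop = FALSE]))
  }
  n <- nrow(halves[[1]])
  means <- sapply(halves, colMeans)
  vars <- sapply(halves, function(m) apply(m, 2, stats::var))
  if (is.null(dim(means))) { means <- matrix(means, nrow = 1); vars <- matrix(vars, nrow = 1) }
  W <- rowMeans(vars)
  B <- n * apply(means, 1, stats::var)
  vhat <- (n - 1) / n * W + B / n
  out <- sqrt(vhat / W)
  out[W < 1e-300] <- NA_real_
  out
}
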