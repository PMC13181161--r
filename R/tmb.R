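# Build the TMB objective for the joint posterior.
#
# Observation rows are stacked biomarker-blockwise (k = 1..K) and the fixed /
# random design matrices are column-blocked in the same order, so the C++
# template never hard-codes K. The per-subject random-effect vector is laid
# out (mu_1..mu_K, sigma_1..sigma_K).

assoc_code <- function(association) {
  match(association, c("cv", "lp", "re"))
}

# number of association coefficients for a given structure
n_alpha <- function(association, designs) {
  if (association == "re") designs$n_re else 2L * designs$K
}

# Column-mean centering of the fixed association designs and of the event
# covariates. This reparameterises the baseline spline to represent the log
# hazard at the average linear predictor, removing the strong posterior
# correlation between the spline level and alpha * (mean predictor) that
# otherwise slows the sampler; alpha, gamma and beta are unchanged. For the
# CV structure the sigma design enters through exp() and is left uncentered
# (centering there would rescale alpha_sigma rather than shift the baseline).
build_tmb_inputs <- function(long, surv, designs, spline, association,
                             priors, rule, event_formula) {
  K <- designs$K
  N <- designs$N
  surv <- surv[match(designs$ids, surv$id), , drop = FALSE]
  if (anyNA(surv$id)) stop("survival table is missing subjects")

  # --- longitudinal stacking ---
  rows <- lapply(designs$mu, `[[`, "rows")
  y <- unlist(lapply(rows, function(r) long$value[r]), use.names = FALSE)
  obs_subj <- unlist(lapply(designs$mu, `[[`, "subj"), use.names = FALSE) - 1L
  blockdiag <- function(blocks, field) {
    mats <- lapply(blocks, `[[`, field)
    nr <- vapply(mats, nrow, integer(1)); nc <- vapply(mats, ncol, integer(1))
    out <- matrix(0, sum(nr), sum(nc))
    ro <- cumsum(c(0L, nr)); co <- cumsum(c(0L, nc))
    for (k in seq_along(mats))
      if (nc[k] > 0)
        out[(ro[k] + 1):ro[k + 1], (co[k] + 1):co[k + 1]] <- mats[[k]]
    out
  }
  Xmu <- blockdiag(designs$mu, "X");    Xsig <- blockdiag(designs$sigma, "X")
  Zmu <- blockdiag(designs$mu, "Z");    Zsig <- blockdiag(designs$sigma, "Z")

  pmu_len <- vapply(designs$mu, function(b) ncol(b$X), integer(1))
  psig_len <- vapply(designs$sigma, function(b) ncol(b$X), integer(1))
  pmu_off <- cumsum(c(0L, pmu_len))[seq_len(K)]
  psig_off <- cumsum(c(0L, psig_len))[seq_len(K)]
  off <- re_offsets(designs)

  # --- event structure ---
  wX <- stats::model.matrix(event_formula, as.data.frame(surv))
  wX <- wX[, colnames(wX) != "(Intercept)", drop = FALSE]
  BT <- bspline_basis(surv$time, spline)
  node_t <- matrix(0, N, rule$Q); qw <- matrix(0, N, rule$Q)
  for (i in seq_len(N)) {
    m <- map_rule(rule, surv$entry[i], surv$time[i])
    node_t[i, ] <- m$times; qw[i, ] <- m$weights
  }
  tq <- as.vector(t(node_t))                    # subject-major node times
  Bq <- bspline_basis(tq, spline)
  subj_all <- seq_len(N)
  subj_q <- rep(subj_all, each = rule$Q)

  # association designs: eta_{psi k} evaluated at event times / nodes
  colblock <- function(psi, subj_idx, times) {
    Xs <- vector("list", K); Zs <- vector("list", K)
    for (k in seq_len(K)) {
      d <- design_at(designs, psi, k, subj_idx, times)
      Xs[[k]] <- d$X; Zs[[k]] <- d$Z
    }
    list(X = do.call(cbind, Xs), Z = do.call(cbind, Zs))
  }
  need_cv <- association %in% c("cv", "lp")
  if (need_cv) {
    amT <- colblock("mu", subj_all, surv$time)
    asT <- colblock("sigma", subj_all, surv$time)
    amQ <- colblock("mu", subj_q, tq)
    asQ <- colblock("sigma", subj_q, tq)
  } else {
    z0 <- function(n, p) matrix(0, n, p)
    amT <- list(X = z0(N, sum(pmu_len)), Z = z0(N, sum(designs$L_mu)))
    asT <- list(X = z0(N, sum(psig_len)), Z = z0(N, sum(designs$L_sig)))
    amQ <- list(X = z0(N * rule$Q, sum(pmu_len)), Z = z0(N * rule$Q, sum(designs$L_mu)))
    asQ <- list(X = z0(N * rule$Q, sum(psig_len)), Z = z0(N * rule$Q, sum(designs$L_sig)))
  }
  ensure <- function(M) if (is.null(M) || ncol(M) == 0) matrix(0, nrow(M), 0) else M

  # decorrelating centering (see note above); centers are data constants
  wX <- ensure(wX)
  w_center <- if (ncol(wX)) colMeans(wX) else numeric(0)
  if (ncol(wX)) wX <- sweep(wX, 2, w_center)
  amu_center <- if (need_cv && nrow(amQ$X)) colMeans(amQ$X) else
    numeric(ncol(amT$X))
  asig_center <- numeric(ncol(asT$X))
  if (need_cv) {
    amT$X <- sweep(amT$X, 2, amu_center)
    amQ$X <- sweep(amQ$X, 2, amu_center)
    if (association == "lp" && nrow(asQ$X)) {
      asig_center <- colMeans(asQ$X)
      asT$X <- sweep(asT$X, 2, asig_center)
      asQ$X <- sweep(asQ$X, 2, asig_center)
    }
  }

  data <- list(
    y = y, obs_subj = obs_subj,
    Xmu = Xmu, Xsig = Xsig, Zmu = Zmu, Zsig = Zsig,
    K = K,
    pmu_off = pmu_off, pmu_len = pmu_len,
    psig_off = psig_off, psig_len = psig_len,
    Lmu_off = off$mu, Lmu_len = designs$L_mu,
    Lsig_off = off$sigma, Lsig_len = designs$L_sig,
    delta = as.numeric(surv$event), w = wX,
    BT = BT, Bq = Bq, qw = qw,
    assoc = assoc_code(association),
    XmuT = amT$X, ZmuT = amT$Z, XsigT = asT$X, ZsigT = asT$Z,
    Xmuq = amQ$X, Zmuq = amQ$Z, Xsigq = asQ$X, Zsigq = asQ$Z,
    Dr = diff_matrix(spline$L, spline$diff_order),
    pen_rank = spline$pen_rank,
    prior_beta_sd = priors$beta_sd, prior_gamma_sd = priors$gamma_sd,
    prior_alpha_sd = priors$alpha_sd,
    tau_df = priors$tau_df, tau_scale = priors$tau_scale,
    cpc_shape = cpc_beta_shapes(designs$n_re, priors$lkj_eta),
    tauh_a = priors$tau_h_shape[1], tauh_b = priors$tau_h_shape[2])

  parameters <- list(
    beta_mu = numeric(sum(pmu_len)),
    beta_sig = numeric(sum(psig_len)),
    gamma_w = numeric(ncol(data$w)),
    alpha = numeric(n_alpha(association, designs)),
    gamma_h0 = numeric(spline$L),
    log_tau = numeric(designs$n_re),
    z_cpc = numeric(designs$n_re * (designs$n_re - 1) / 2),
    logit_tau_h = 0,
    b_raw = matrix(0, N, designs$n_re))

  list(data = data, parameters = parameters, surv = surv,
       event_names = colnames(wX),
       centers = list(w = w_center, assoc_mu = amu_center,
                      assoc_sigma = asig_center))
}

# map from alpha index to whether it is a sigma-association coefficient
alpha_sigma_mask <- function(association, designs) {
  if (association == "re")
    c(rep(FALSE, sum(designs$L_mu)), rep(TRUE, sum(designs$L_sig)))
  else c(rep(FALSE, designs$K), rep(TRUE, designs$K))
}

make_objective <- function(inputs, map = NULL) {
  TMB::MakeADFun(data = inputs$data, parameters = inputs$parameters,
                 map = map, DLL = "jmwiv", silent = TRUE)
}

# human-readable names for the sampled model parameters (excluding b_raw)
tmb_par_names <- function(inputs, designs, association) {
  K <- designs$K
  nm_block <- function(prefix, blocks) {
    unlist(lapply(seq_along(blocks), function(k) {
      cn <- colnames(blocks[[k]]$X)
      paste0(prefix, k, "_", gsub("[() ]", "", cn))
    }))
  }
  re_labels <- unlist(lapply(c("mu", "sigma"), function(psi) {
    L <- if (psi == "mu") designs$L_mu else designs$L_sig
    unlist(lapply(seq_len(K), function(k)
      if (L[k] == 0) character(0)
      else if (L[k] == 1) paste0(psi, k)
      else paste0(psi, k, "_", seq_len(L[k]))))
  }))
  alpha_nm <- if (association == "re") paste0("alpha_", re_labels)
  else c(paste0("alpha_mu", seq_len(K)), paste0("alpha_sigma", seq_len(K)))
  pairs <- if (designs$n_re > 1) cpc_pairs(designs$n_re) else NULL
  list(beta_mu = nm_block("beta_mu", designs$mu),
       beta_sig = nm_block("beta_sigma", designs$sigma),
       gamma_w = if (length(inputs$event_names))
         paste0("gamma_", inputs$event_names) else character(0),
       alpha = alpha_nm,
       gamma_h0 = paste0("gamma_h0_", seq_len(ncol(inputs$data$BT))),
       log_tau = paste0("tau_", re_labels),
       z_cpc = if (!is.null(pairs))
         paste0("rho_", re_labels[pairs[, 1]], "_", re_labels[pairs[, 2]])
       else character(0),
       logit_tau_h = "tau_h",
       re_labels = re_labels)
}
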