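// Joint posterior of the location-scale joint model (negative log density,
// unconstrained parameterisation). Autodiff through TMB supplies the
// gradients consumed by the package's NUTS sampler.
//
// Parameter transforms handled here:
//   tau      = exp(log_tau)                       (+ log Jacobian)
//   P        from canonical partial correlations  x = tanh(z_cpc), C-vine
//   tau_h    = inverse-logit(logit_tau_h)         (+ log Jacobian)
//   b_i      = diag(tau) * chol(P) * z_i          (non-centered)

#define TMB_LIB_INIT R_init_jmwiv
#include <TMB.hpp>

template <class Type>
Type half_t_lpdf(Type x, Type df, Type scale) {
  // density of |scale * t_df|, normalised
  Type z = x / scale;
  return log(Type(2.0)) + lgamma((df + 1) / 2) - lgamma(df / 2)
       - Type(0.5) * log(df * M_PI) - log(scale)
       - (df + 1) / 2 * log(Type(1.0) + z * z / df);
}

template <class Type>
Type objective_function<Type>::operator()() {
  // ---- longitudinal data ----
  DATA_VECTOR(y);            // all observations, stacked biomarker-blockwise
  DATA_IVECTOR(obs_subj);    // 0-based subject of each observation
  DATA_MATRIX(Xmu);          // column-blocked fixed designs (mean)
  DATA_MATRIX(Xsig);         // column-blocked fixed designs (log SD)
  DATA_MATRIX(Zmu);          // column-blocked random designs (mean)
  DATA_MATRIX(Zsig);         // column-blocked random designs (log SD)
  DATA_INTEGER(K);
  DATA_IVECTOR(pmu_off);  DATA_IVECTOR(pmu_len);   // beta_mu column blocks
  DATA_IVECTOR(psig_off); DATA_IVECTOR(psig_len);  // beta_sig column blocks
  DATA_IVECTOR(Lmu_off);  DATA_IVECTOR(Lmu_len);   // b columns: mu blocks
  DATA_IVECTOR(Lsig_off); DATA_IVECTOR(Lsig_len);  // b columns: sigma blocks

  // ---- event data ----
  DATA_VECTOR(delta);
  DATA_MATRIX(w);            // baseline covariates (may have 0 columns)
  DATA_MATRIX(BT);           // spline basis at observed times, N x L
  DATA_MATRIX(Bq);           // spline basis at quadrature nodes, (N*Q) x L
  DATA_MATRIX(qw);           // scaled quadrature weights, N x Q
  DATA_INTEGER(assoc);       // 1 = CV, 2 = LP, 3 = RE
  DATA_MATRIX(XmuT);  DATA_MATRIX(ZmuT);   // association designs at T_i
  DATA_MATRIX(XsigT); DATA_MATRIX(ZsigT);
  DATA_MATRIX(Xmuq);  DATA_MATRIX(Zmuq);   // association designs at nodes
  DATA_MATRIX(Xsigq); DATA_MATRIX(Zsigq);

  // ---- penalty and prior hyperparameters ----
  DATA_MATRIX(Dr);           // difference penalty matrix
  DATA_SCALAR(pen_rank);
  DATA_SCALAR(prior_beta_sd);
  DATA_SCALAR(prior_gamma_sd);
  DATA_SCALAR(prior_alpha_sd);
  DATA_SCALAR(tau_df);
  DATA_SCALAR(tau_scale);
  DATA_VECTOR(cpc_shape);    // Beta shapes of the vine partial correlations
  DATA_SCALAR(tauh_a);
  DATA_SCALAR(tauh_b);

  // ---- parameters ----
  PARAMETER_VECTOR(beta_mu);
  PARAMETER_VECTOR(beta_sig);
  PARAMETER_VECTOR(gamma_w);
  PARAMETER_VECTOR(alpha);
  PARAMETER_VECTOR(gamma_h0);
  PARAMETER_VECTOR(log_tau);
  PARAMETER_VECTOR(z_cpc);
  PARAMETER(logit_tau_h);
  PARAMETER_MATRIX(b_raw);   // N x n_re standard-normal innovations

  int N = b_raw.rows(), n_re = b_raw.cols();
  int nobs = y.size(), Q = qw.cols();
  int Lmu_tot = Zmu.cols();
  Type nll = 0;
  const Type half_l2pi = Type(0.5) * log(2 * M_PI);

  // ---- transforms ----
  vector<Type> tau = exp(log_tau);

  // canonical partial correlations -> full correlation matrix (C-vine)
  matrix<Type> pc(n_re, n_re);
  pc.setZero();
  {
    int idx = 0;
    for (int i = 0; i < n_re - 1; i++)
      for (int j = i + 1; j < n_re; j++) pc(i, j) = tanh(z_cpc(idx++));
  }
  matrix<Type> P(n_re, n_re);
  P.setIdentity();
  for (int i = 0; i < n_re - 1; i++)
    for (int j = i + 1; j < n_re; j++) {
      Type rho = pc(i, j);
      for (int l = i - 1; l >= 0; l--)
        rho = rho * sqrt((1 - pc(l, i) * pc(l, i)) * (1 - pc(l, j) * pc(l, j)))
            + pc(l, i) * pc(l, j);
      P(i, j) = rho;
      P(j, i) = rho;
    }

  // Cholesky of P (small, hand-rolled so it stays on the AD tape)
  matrix<Type> Lc(n_re, n_re);
  Lc.setZero();
  for (int i = 0; i < n_re; i++) {
    for (int j = 0; j <= i; j++) {
      Type s = P(i, j);
      for (int l = 0; l < j; l++) s -= Lc(i, l) * Lc(j, l);
      if (i == j) Lc(i, i) = sqrt(s);
      else        Lc(i, j) = s / Lc(j, j);
    }
  }

  // non-centered random effects: b = b_raw * Lc' * diag(tau)
  matrix<Type> b = b_raw * Lc.transpose();
  for (int c = 0; c < n_re; c++) b.col(c) *= tau(c);

  Type tau_h = invlogit(logit_tau_h);

  // ---- longitudinal log-likelihood ----
  vector<Type> ll_subj(N);
  ll_subj.setZero();
  vector<Type> eta_mu = Xmu * beta_mu;
  vector<Type> eta_sig = Xsig * beta_sig;
  int Lsig_tot = Zsig.cols();
  for (int r = 0; r < nobs; r++) {
    int i = obs_subj(r);
    for (int c = 0; c < Lmu_tot; c++)  eta_mu(r)  += Zmu(r, c)  * b(i, c);
    for (int c = 0; c < Lsig_tot; c++) eta_sig(r) += Zsig(r, c) * b(i, Lmu_tot + c);
    Type res = y(r) - eta_mu(r);
    Type ll = -half_l2pi - eta_sig(r)
            - Type(0.5) * res * res * exp(-2 * eta_sig(r));
    ll_subj(i) += ll;
  }
  nll -= ll_subj.sum();

  // ---- association term at event times and quadrature nodes ----
  vector<Type> wg(N);
  if (w.cols() > 0) wg = w * gamma_w; else wg.setZero();

  vector<Type> aT(N), aQ(N * Q);
  aT.setZero();
  aQ.setZero();
  if (assoc == 3) {                     // RE: alpha' b_i, constant in time
    for (int i = 0; i < N; i++) {
      Type s = 0;
      for (int c = 0; c < n_re; c++) s += alpha(c) * b(i, c);
      aT(i) = s;
      for (int q = 0; q < Q; q++) aQ(i * Q + q) = s;
    }
  } else {                              // CV (1) or LP (2)
    for (int k = 0; k < K; k++) {
      Type amu = alpha(k), asig = alpha(K + k);
      vector<Type> bmu_k  = (XmuT.middleCols(pmu_off(k), pmu_len(k))
                             * beta_mu.segment(pmu_off(k), pmu_len(k)).matrix()).array();
      vector<Type> bsig_k = (XsigT.middleCols(psig_off(k), psig_len(k))
                             * beta_sig.segment(psig_off(k), psig_len(k)).matrix()).array();
      vector<Type> qmu_k  = (Xmuq.middleCols(pmu_off(k), pmu_len(k))
                             * beta_mu.segment(pmu_off(k), pmu_len(k)).matrix()).array();
      vector<Type> qsig_k = (Xsigq.middleCols(psig_off(k), psig_len(k))
                             * beta_sig.segment(psig_off(k), psig_len(k)).matrix()).array();
      for (int i = 0; i < N; i++) {
        Type emu = bmu_k(i), esig = bsig_k(i);
        for (int c = 0; c < Lmu_len(k); c++)
          emu += ZmuT(i, Lmu_off(k) + c) * b(i, Lmu_off(k) + c);
        for (int c = 0; c < Lsig_len(k); c++)
          esig += ZsigT(i, Lsig_off(k) - Lmu_tot + c) * b(i, Lsig_off(k) + c);
        aT(i) += amu * emu + asig * (assoc == 1 ? exp(esig) : esig);
        for (int q = 0; q < Q; q++) {
          int r = i * Q + q;
          Type nmu = qmu_k(r), nsig = qsig_k(r);
          for (int c = 0; c < Lmu_len(k); c++)
            nmu += Zmuq(r, Lmu_off(k) + c) * b(i, Lmu_off(k) + c);
          for (int c = 0; c < Lsig_len(k); c++)
            nsig += Zsigq(r, Lsig_off(k) - Lmu_tot + c) * b(i, Lsig_off(k) + c);
          aQ(r) += amu * nmu + asig * (assoc == 1 ? exp(nsig) : nsig);
        }
      }
    }
  }

  // ---- event log-likelihood: delta * log h(T) - cumulative hazard ----
  vector<Type> lh0T = BT * gamma_h0;
  vector<Type> lh0q = Bq * gamma_h0;
  for (int i = 0; i < N; i++) {
    Type cum = 0;
    for (int q = 0; q < Q; q++)
      cum += qw(i, q) * exp(lh0q(i * Q + q) + wg(i) + aQ(i * Q + q));
    Type ll = delta(i) * (lh0T(i) + wg(i) + aT(i)) - cum;
    ll_subj(i) += ll;
    nll -= ll;
  }

  // ---- random-effect innovations ----
  for (int i = 0; i < N; i++)
    for (int c = 0; c < n_re; c++)
      nll += half_l2pi + Type(0.5) * b_raw(i, c) * b_raw(i, c);

  // ---- priors ----
  for (int j = 0; j < beta_mu.size(); j++)
    nll -= dnorm(beta_mu(j), Type(0), prior_beta_sd, true);
  for (int j = 0; j < beta_sig.size(); j++)
    nll -= dnorm(beta_sig(j), Type(0), prior_beta_sd, true);
  for (int j = 0; j < gamma_w.size(); j++)
    nll -= dnorm(gamma_w(j), Type(0), prior_gamma_sd, true);
  for (int j = 0; j < alpha.size(); j++)
    nll -= dnorm(alpha(j), Type(0), prior_alpha_sd, true);

  // Bayesian P-spline prior on the log baseline hazard coefficients
  vector<Type> dg = Dr * gamma_h0;
  nll -= pen_rank / 2 * log(tau_h) - tau_h / 2 * (dg * dg).sum();

  // half-t on random-effect SDs (+ log-tau Jacobian)
  for (int j = 0; j < n_re; j++)
    nll -= half_t_lpdf(tau(j), tau_df, tau_scale) + log_tau(j);

  // LKJ on P through its vine partial correlations (+ tanh Jacobian)
  {
    int idx = 0;
    for (int i = 0; i < n_re - 1; i++)
      for (int j = i + 1; j < n_re; j++) {
        Type x = pc(i, j), a = cpc_shape(idx++);
        nll -= lgamma(2 * a) - 2 * lgamma(a)
             + (a - 1) * (log((1 + x) / 2) + log((1 - x) / 2))
             - log(Type(2.0)) + log(1 - x * x);
      }
  }

  // Beta prior on tau_h (+ logit Jacobian)
  nll -= dbeta(tau_h, tauh_a, tauh_b, true) + log(tau_h * (1 - tau_h));

  REPORT(ll_subj);
  REPORT(b);
  REPORT(tau);
  REPORT(P);
  REPORT(tau_h);
  return nll;
}
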