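// Joint log posterior of the hierarchical population-reconstruction model,
// on unconstrained sampling coordinates (log / logit / stick-breaking
// transforms with their Jacobians), with three exact or near-exact
// reductions chosen for sampling efficiency:
//   * per-unit imputed counts are collapsed to their per-year totals
//     (gammas sharing a rate sum to a gamma; exact, reconstructable);
//   * the per-unit log-intensity walks are sampled non-centred
//     (standardised innovations), which removes the funnel between the
//     innovation SDs and the field; the common drifts stay centred
//     because the p parallel units inform them strongly.
#include <TMB.hpp>

// Smooth positivity barrier: below eps the value is bent to stay positive
// and a quadratic penalty is added, so proposals with a non-positive
// transition mean are rejected as divergent instead of producing NaN
// gradients (CppAD conditionals evaluate both branches).
template <class Type>
Type posbarrier(Type x, Type eps, Type &pen) {
  pen += CppAD::CondExpLt(x, eps, Type(0.01) * pow(x - eps, 2), Type(0));
  return CppAD::CondExpGe(x, eps, x, eps / (Type(2) - x / eps));
}

template <class Type>
Type objective_function<Type>::operator()() {
  DATA_MATRIX(b_obs);        // T_e x p, 0 where unavailable, zeros offset
  DATA_MATRIX(d_obs);
  DATA_MATRIX(avail_b);      // 0/1 masks
  DATA_MATRIX(avail_d);
  DATA_VECTOR(s);            // casualties per event year
  DATA_IVECTOR(census_idx);  // 0-based indices into mu
  DATA_VECTOR(census_val);
  DATA_INTEGER(crisis_e);    // 0-based event index of crisis year, or -1
  DATA_VECTOR(years_e);      // event years (calendar)
  DATA_SCALAR(t_start);
  DATA_SCALAR(midpoint_span);
  DATA_VECTOR(nmiss_b);      // missing-unit counts per event year
  DATA_VECTOR(nmiss_d);

  // prior hyperparameters (gamma priors shape-rate; normals mean-sd)
  DATA_VECTOR(pr_psi_mu);
  DATA_VECTOR(pr_sigma_c);
  DATA_VECTOR(pr_pi);        // beta (alpha, beta)
  DATA_VECTOR(pr_log_phi_d);
  DATA_VECTOR(pr_psi_bd);
  DATA_VECTOR(pr_sigma_nu);
  DATA_VECTOR(pr_sigma_eta);
  DATA_VECTOR(pr_r);
  DATA_VECTOR(pr_m_tilde);   // beta
  DATA_VECTOR(pr_lambda_end);// beta
  DATA_VECTOR(pr_dir);       // Dirichlet weights, length 3
  DATA_VECTOR(pr_mu_init);   // gamma
  DATA_VECTOR(init_nu_b);    // (mean, sd)
  DATA_VECTOR(init_nu_d);
  DATA_VECTOR(init_eta);

  // Population path, non-centred: mu_1 on the log scale plus
  // standardised log-increments w scaled by the local transition SD
  // (1 / sqrt(psi_mu * mu_t)), which removes both the scale gap between
  // the path and the unit-scale innovations and the psi_mu funnel.
  PARAMETER(log_mu1);
  PARAMETER_VECTOR(w_mu);          // length T_e
  PARAMETER(t_log_sigma_c);
  PARAMETER(t_log_psi_mu);
  PARAMETER(t_logit_pi);
  PARAMETER(log_phi_d);            // sampled directly on log scale
  PARAMETER(t_log_psi_bd);
  PARAMETER(t_log_sigma_b_nu);
  PARAMETER(t_log_sigma_d_nu);
  PARAMETER(t_log_sigma_b_eta);
  PARAMETER(t_log_sigma_d_eta);
  PARAMETER(t_log_r_b);
  PARAMETER(t_log_r_d);
  PARAMETER(t_logit_mt_b);
  PARAMETER(t_logit_mt_d);
  PARAMETER(t_logit_lam_end);
  PARAMETER_VECTOR(t_stick);       // length 2, simplex transform for a
  // Per-unit walks non-centred (standardised innovations z); common
  // drifts centred.
  PARAMETER_MATRIX(z_nu_b);        // T_e x p
  PARAMETER_MATRIX(z_nu_d);
  PARAMETER_VECTOR(eta_b);         // T_e common drifts
  PARAMETER_VECTOR(eta_d);
  PARAMETER_VECTOR(log_sb);        // imputed baptism totals per event year
  PARAMETER_VECTOR(log_sd_);       // imputed burial totals

  int T_e = b_obs.rows();
  int p = b_obs.cols();
  Type lp = 0;    // log posterior (incl. Jacobians); return -lp + penalty
  Type pen = 0;

  // ---- transforms with Jacobians, plus scalar priors -------------------
  Type sigma_c = exp(t_log_sigma_c);
  lp += dgamma(sigma_c, pr_sigma_c(0), Type(1) / pr_sigma_c(1), true)
        + t_log_sigma_c;
  Type psi_mu = exp(t_log_psi_mu);
  lp += dgamma(psi_mu, pr_psi_mu(0), Type(1) / pr_psi_mu(1), true)
        + t_log_psi_mu;
  Type pi_ = invlogit(t_logit_pi);
  lp += dbeta(pi_, pr_pi(0), pr_pi(1), true) + log(pi_) + log(1 - pi_);
  Type phi_d = exp(log_phi_d);
  lp += dnorm(log_phi_d, pr_log_phi_d(0), pr_log_phi_d(1), true);
  Type psi_bd = exp(t_log_psi_bd);
  lp += dgamma(psi_bd, pr_psi_bd(0), Type(1) / pr_psi_bd(1), true)
        + t_log_psi_bd;
  Type sigma_b_nu = exp(t_log_sigma_b_nu);
  lp += dgamma(sigma_b_nu, pr_sigma_nu(0), Type(1) / pr_sigma_nu(1), true)
        + t_log_sigma_b_nu;
  Type sigma_d_nu = exp(t_log_sigma_d_nu);
  lp += dgamma(sigma_d_nu, pr_sigma_nu(0), Type(1) / pr_sigma_nu(1), true)
        + t_log_sigma_d_nu;
  Type sigma_b_eta = exp(t_log_sigma_b_eta);
  lp += dgamma(sigma_b_eta, pr_sigma_eta(0), Type(1) / pr_sigma_eta(1), true)
        + t_log_sigma_b_eta;
  Type sigma_d_eta = exp(t_log_sigma_d_eta);
  lp += dgamma(sigma_d_eta, pr_sigma_eta(0), Type(1) / pr_sigma_eta(1), true)
        + t_log_sigma_d_eta;
  // growth rates bounded away from zero so the endpoint rescaling of the
  // coverage curve cannot degenerate
  Type r_b = Type(1e-6) + exp(t_log_r_b);
  lp += dgamma(r_b, pr_r(0), Type(1) / pr_r(1), true) + t_log_r_b;
  Type r_d = Type(1e-6) + exp(t_log_r_d);
  lp += dgamma(r_d, pr_r(0), Type(1) / pr_r(1), true) + t_log_r_d;
  Type mt_b = invlogit(t_logit_mt_b);
  lp += dbeta(mt_b, pr_m_tilde(0), pr_m_tilde(1), true)
        + log(mt_b) + log(1 - mt_b);
  Type mt_d = invlogit(t_logit_mt_d);
  lp += dbeta(mt_d, pr_m_tilde(0), pr_m_tilde(1), true)
        + log(mt_d) + log(1 - mt_d);
  Type lam_end = invlogit(t_logit_lam_end);
  lp += dbeta(lam_end, pr_lambda_end(0), pr_lambda_end(1), true)
        + log(lam_end) + log(1 - lam_end);

  // stick-breaking simplex (a1, a2, a3) with Dirichlet prior
  Type zs1 = invlogit(t_stick(0) - log(Type(2)));  // centred: K - k = 2
  Type zs2 = invlogit(t_stick(1));
  Type a1 = zs1;
  Type a2 = (1 - a1) * zs2;
  Type a3 = 1 - a1 - a2;
  lp += log(zs1) + log(1 - zs1) + log(zs2) + log(1 - zs2) + log(1 - a1);
  vector<Type> a(3); a << a1, a2, a3;
  lp += lgamma(pr_dir.sum());
  for (int k = 0; k < 3; ++k) {
    lp += (pr_dir(k) - 1) * log(a(k)) - lgamma(pr_dir(k));
  }

  // ---- coverage curves -------------------------------------------------
  Type m_b = t_start + midpoint_span * mt_b;
  Type m_d = t_start + midpoint_span * mt_d;
  Type lam_start_b = (a1 + a2) * lam_end;
  Type lam_start_d = a1 * lam_end;
  vector<Type> lam_b(T_e), lam_d(T_e);
  Type raw_b0 = invlogit(r_b * (years_e(0) - m_b));
  Type raw_bT = invlogit(r_b * (years_e(T_e - 1) - m_b));
  Type raw_d0 = invlogit(r_d * (years_e(0) - m_d));
  Type raw_dT = invlogit(r_d * (years_e(T_e - 1) - m_d));
  for (int t = 0; t < T_e; ++t) {
    Type rb = invlogit(r_b * (years_e(t) - m_b));
    Type rd = invlogit(r_d * (years_e(t) - m_d));
    lam_b(t) = (rb - raw_b0) / (raw_bT - raw_b0) * (lam_end - lam_start_b)
               + lam_start_b;
    lam_d(t) = (rd - raw_d0) / (raw_dT - raw_d0) * (lam_end - lam_start_d)
               + lam_start_d;
  }

  // ---- latent walks: drift centred, per-unit innovations non-centred --
  lp += dnorm(eta_b(0), init_eta(0), init_eta(1), true)
        + dnorm(eta_d(0), init_eta(0), init_eta(1), true);
  for (int t = 1; t < T_e; ++t) {
    lp += dnorm(eta_b(t) - eta_b(t - 1), Type(0), sigma_b_eta, true)
          + dnorm(eta_d(t) - eta_d(t - 1), Type(0), sigma_d_eta, true);
  }
  matrix<Type> nu_b(T_e, p), nu_d(T_e, p);
  for (int i = 0; i < p; ++i) {
    nu_b(0, i) = init_nu_b(0) + init_nu_b(1) * z_nu_b(0, i);
    nu_d(0, i) = init_nu_d(0) + init_nu_d(1) * z_nu_d(0, i);
    lp += dnorm(z_nu_b(0, i), Type(0), Type(1), true)
          + dnorm(z_nu_d(0, i), Type(0), Type(1), true);
    for (int t = 1; t < T_e; ++t) {
      nu_b(t, i) = nu_b(t - 1, i) + eta_b(t) + sigma_b_nu * z_nu_b(t, i);
      nu_d(t, i) = nu_d(t - 1, i) + eta_d(t) + sigma_d_nu * z_nu_d(t, i);
      lp += dnorm(z_nu_b(t, i), Type(0), Type(1), true)
            + dnorm(z_nu_d(t, i), Type(0), Type(1), true);
    }
  }

  // ---- parish observation terms and imputed totals ---------------------
  vector<Type> Sb(T_e), Sd(T_e), beta(T_e), delta(T_e);
  for (int t = 0; t < T_e; ++t) {
    Type cf_d = (t == crisis_e) ? phi_d : Type(1);
    Type shape_miss_b = 0, shape_miss_d = 0, obs_sum_b = 0, obs_sum_d = 0;
    for (int i = 0; i < p; ++i) {
      if (avail_b(t, i) > 0.5) {
        lp += dgamma(b_obs(t, i), psi_bd * exp(nu_b(t, i)),
                     Type(1) / psi_bd, true);
        obs_sum_b += b_obs(t, i);
      } else {
        shape_miss_b += psi_bd * exp(nu_b(t, i));
      }
      if (avail_d(t, i) > 0.5) {
        lp += dgamma(d_obs(t, i), psi_bd * cf_d * exp(nu_d(t, i)),
                     Type(1) / psi_bd, true);
        obs_sum_d += d_obs(t, i);
      } else {
        shape_miss_d += psi_bd * cf_d * exp(nu_d(t, i));
      }
    }
    if (nmiss_b(t) > 0.5) {
      Sb(t) = exp(log_sb(t));
      lp += dgamma(Sb(t), shape_miss_b, Type(1) / psi_bd, true)
            + log_sb(t);
    } else {
      Sb(t) = 0;
      lp += dnorm(log_sb(t), Type(0), Type(1), true);  // inert placeholder
    }
    if (nmiss_d(t) > 0.5) {
      Sd(t) = exp(log_sd_(t));
      lp += dgamma(Sd(t), shape_miss_d, Type(1) / psi_bd, true)
            + log_sd_(t);
    } else {
      Sd(t) = 0;
      lp += dnorm(log_sd_(t), Type(0), Type(1), true);
    }
    beta(t) = (obs_sum_b + Sb(t)) / lam_b(t);
    delta(t) = (obs_sum_d + Sd(t)) / lam_d(t);
  }

  // ---- population path -------------------------------------------------
  vector<Type> mu(T_e + 1);
  mu(0) = exp(log_mu1);
  lp += log_mu1;  // Jacobian of the log transform of mu_1
  lp += dgamma(mu(0), pr_mu_init(0), Type(1) / pr_mu_init(1), true);
  for (int t = 0; t < T_e; ++t) {
    Type log_mu_t = log(mu(t));
    Type scale_t = Type(1) / sqrt(psi_mu * mu(t));
    Type log_mu_next = log_mu_t + w_mu(t) * scale_t;
    mu(t + 1) = exp(log_mu_next);
    // triangular-map Jacobian: d mu_(t+1) / d w_t = mu_(t+1) * scale_t
    lp += log_mu_next + log(scale_t);
    Type mean_t = (t == crisis_e)
      ? pi_ * mu(t - 1)
      : mu(t) + beta(t) - delta(t) - s(t);
    Type mean_safe = posbarrier(mean_t, Type(1), pen);
    lp += dgamma(mu(t + 1), psi_mu * mean_safe, Type(1) / psi_mu, true);
  }

  // ---- censuses --------------------------------------------------------
  for (int k = 0; k < census_idx.size(); ++k) {
    lp += dnorm(census_val(k), mu(census_idx(k)), sigma_c, true);
  }

  // ---- derived crisis coefficient and reports --------------------------
  Type phi_mu = 0;
  if (crisis_e >= 0) {
    phi_mu = (mu(crisis_e) + beta(crisis_e) - s(crisis_e)
              - pi_ * mu(crisis_e - 1)) / delta(crisis_e);
  }

  REPORT(mu); REPORT(beta); REPORT(delta);
  REPORT(lam_b); REPORT(lam_d); REPORT(phi_mu);
  REPORT(sigma_c); REPORT(psi_mu); REPORT(pi_); REPORT(phi_d);
  REPORT(psi_bd); REPORT(sigma_b_nu); REPORT(sigma_d_nu);
  REPORT(sigma_b_eta); REPORT(sigma_d_eta);
  REPORT(r_b); REPORT(r_d); REPORT(m_b); REPORT(m_d);
  REPORT(a); REPORT(lam_end);
  REPORT(nu_b); REPORT(nu_d); REPORT(eta_b); REPORT(eta_d);
  REPORT(Sb); REPORT(Sd);

  return -lp + pen;
}
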