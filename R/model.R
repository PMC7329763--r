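#' Logistic register-coverage curve with fixed endpoints
#'
#' The raw logistic curve `1 / (1 + exp(-r (t - m)))` is affinely rescaled
#' so that its value at the first year of `years` equals `lam_start` and
#' at the last year equals `lam_end`, exactly. The curve models the
#' fraction of true vital events captured by the surviving registers.
#'
#' @param r Logistic growth rate per year (> 0).
#' @param m Midpoint (calendar year).
#' @param lam_start,lam_end Coverage at the first and last year, in (0, 1].
#' @param years Integer vector of years (ordered).
#' @return Numeric coverage series over `years`.
#' @export
lambda_curve <- function(r, m, lam_start, lam_end, years) {
  stopifnot(r > 0, lam_start > 0, lam_start <= 1, lam_end > 0, lam_end <= 1)
  raw <- stats::plogis(r * (years - m))
  denom <- raw[length(raw)] - raw[1]
  if (abs(denom) < 1e-12) {
    stop("degenerate logistic curve: endpoints coincide (r too small ",
         "or span too short)")
  }
  (raw - raw[1]) / denom * (lam_end - lam_start) + lam_start
}

#' Crisis-year mortality correction coefficient
#'
#' Returns the factor phi_mu by which the registered crisis-year deaths
#' must be scaled so that the population transition mean equals
#' `pi * mu_1695`, i.e. the value solving
#' `mu_1696 + beta_1697 - phi_mu * delta_1697 - s_1697 = pi * mu_1695`.
#' If the resulting transition mean is non-positive the state has zero
#' probability; the caller's transition density returns `-Inf` there.
#'
#' @param mu_1696 Population the year before the crisis.
#' @param beta_1697 Aggregated births in the crisis year.
#' @param s_1697 Military casualties in the crisis year.
#' @param pi Crisis survival ratio in (0, 1).
#' @param mu_1695 Population two years before the crisis.
#' @param delta_1697 Aggregated registered deaths in the crisis year (> 0).
#' @return The scalar phi_mu.
#' @export
famine_phi_mu <- function(mu_1696, beta_1697, s_1697, pi, mu_1695,
                          delta_1697) {
  if (delta_1697 <= 0) stop("delta_1697 must be positive")
  (mu_1696 + beta_1697 - s_1697 - pi * mu_1695) / delta_1697
}

#' Gamma population-transition log density
#'
#' `mu_t ~ Gamma(psi_mu * (mu_prev + beta_t - delta_t - s_t), psi_mu)`
#' (shape--rate), so the implied mean is the accounting balance
#' `mu_prev + beta_t - delta_t - s_t` and the variance is mean / psi_mu.
#' A non-positive shape (deaths exceeding the population balance) has
#' zero probability and returns `-Inf`.
#'
#' @param mu_t Proposed population at year t (> 0).
#' @param mu_prev Population at year t - 1.
#' @param beta_t,delta_t Aggregated births and deaths at year t.
#' @param s_t Military casualties at year t.
#' @param psi_mu Transition rate parameter (> 0).
#' @return Log density (scalar; `-Inf` outside the support).
#' @export
transition_logpdf <- function(mu_t, mu_prev, beta_t, delta_t, s_t, psi_mu) {
  stopifnot(psi_mu > 0)
  shape <- psi_mu * (mu_prev + beta_t - delta_t - s_t)
  if (!is.finite(shape) || shape <= 0 || mu_t <= 0) return(-Inf)
  stats::dgamma(mu_t, shape = shape, rate = psi_mu, log = TRUE)
}

#' Initial-population log density
#'
#' Gamma prior (shape--rate) for the first year of the series; the
#' historical default Gamma(215, 0.0005) has mean 430,000 and SD 29,326.
#'
#' @param mu Initial population value.
#' @param shape,rate Gamma hyperparameters.
#' @export
initial_pop_logpdf <- function(mu, shape = 215, rate = 5e-4) {
  if (mu <= 0) return(-Inf)
  stats::dgamma(mu, shape = shape, rate = rate, log = TRUE)
}

#' Census-benchmark log density
#'
#' `C_t ~ N(mu_t, sigma_c^2)`: the enumerated census is the latent
#' population plus homoskedastic measurement noise.
#'
#' @param C_t Enumerated census population.
#' @param mu_t Latent population at the census year.
#' @param sigma_c Census noise SD (> 0).
#' @export
census_logpdf <- function(C_t, mu_t, sigma_c) {
  stopifnot(sigma_c > 0)
  stats::dnorm(C_t, mean = mu_t, sd = sigma_c, log = TRUE)
}

#' Aggregate observed and imputed counts to a model-scale vital total
#'
#' `beta_t = (sum(observed) + sum(imputed)) / lambda_t`: the coverage
#' coefficient inflates the register total to the estimated true total.
#'
#' @param observed Observed counts for the units with records at year t.
#' @param imputed Imputed counts for the units without records.
#' @param lambda_t Coverage coefficient in (0, 1].
#' @export
aggregate_vital <- function(observed, imputed, lambda_t) {
  if (lambda_t <= 0) stop("lambda_t must be positive")
  (sum(observed) + sum(imputed)) / lambda_t
}

#' Parish-level count log density
#'
#' `count ~ Gamma(psi_bd * crisis_factor * exp(nu), psi_bd)` (shape--rate):
#' a continuous gamma observation model around the latent log intensity
#' nu, with implied mean `crisis_factor * exp(nu)`. The same density is
#' used for observed counts (data term) and imputed counts (latent term).
#' `crisis_factor` is 1 except for burials in the crisis year, where it is
#' the parish-level death inflation phi_d.
#'
#' @param count Positive count (observed zeros must be offset upstream).
#' @param nu Latent log intensity.
#' @param psi_bd Rate parameter (> 0).
#' @param crisis_factor Multiplicative shape inflation (default 1).
#' @return Log density, vectorised over `count`/`nu`.
#' @export
parish_obs_logpdf <- function(count, nu, psi_bd, crisis_factor = 1) {
  stopifnot(psi_bd > 0, crisis_factor > 0)
  stats::dgamma(count, shape = psi_bd * crisis_factor * exp(nu),
                rate = psi_bd, log = TRUE)
}

#' Latent log-intensity random-walk log density
#'
#' Joint density of the parish log intensities `nu` (matrix, years x
#' units) and their common drift `eta` (vector over years):
#' `nu[t, i] ~ N(nu[t-1, i] + eta[t], sigma_nu^2)`,
#' `eta[t] ~ N(eta[t-1], sigma_eta^2)`, with initial terms
#' `nu[1, i] ~ N(nu_init[1], nu_init[2]^2)` and
#' `eta[1] ~ N(eta_init[1], eta_init[2]^2)` (second entries are SDs).
#'
#' @param nu Matrix of log intensities (years in rows).
#' @param eta Drift vector, one entry per row of `nu`.
#' @param sigma_nu,sigma_eta Innovation SDs (> 0).
#' @param nu_init,eta_init Length-2 `(mean, sd)` of the initial terms.
#' @export
latent_walk_logpdf <- function(nu, eta, sigma_nu, sigma_eta,
                               nu_init = c(3.8, 0.5),
                               eta_init = c(0, 0.01)) {
  stopifnot(sigma_nu > 0, sigma_eta > 0)
  nu <- as.matrix(nu)
  T_e <- nrow(nu)
  stopifnot(length(eta) == T_e)
  lp <- stats::dnorm(eta[1], eta_init[1], eta_init[2], log = TRUE) +
    sum(stats::dnorm(nu[1, ], nu_init[1], nu_init[2], log = TRUE))
  if (T_e > 1) {
    lp <- lp + sum(stats::dnorm(diff(eta), 0, sigma_eta, log = TRUE))
    inc <- nu[-1, , drop = FALSE] - nu[-T_e, , drop = FALSE] - eta[-1]
    lp <- lp + sum(stats::dnorm(inc, 0, sigma_nu, log = TRUE))
  }
  lp
}

# Dirichlet log density (for the coverage-share prior).
.ddirichlet_log <- function(x, alpha) {
  if (any(x <= 0) || abs(sum(x) - 1) > 1e-9) return(-Inf)
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

# Coverage series for both event types from the model parameters.
.lambda_series <- function(params, config) {
  lam_end <- params$lambda_end
  lam_start_b <- (params$a[1] + params$a[2]) * lam_end
  lam_start_d <- params$a[1] * lam_end
  list(
    b = lambda_curve(params$r_b, params$m_b, lam_start_b, lam_end,
                     config$event_years),
    d = lambda_curve(params$r_d, params$m_d, lam_start_d, lam_end,
                     config$event_years)
  )
}

# Sum of log prior densities over the time-invariant parameters. The
# midpoint prior is evaluated on the scaled midpoint
# m_tilde = (m - t_start) / midpoint_span.
.prior_logpdf <- function(params, config) {
  pr <- config$priors
  pi_ab <- beta_from_mean_precision(pr$pi_mean, pr$pi_precision)
  mt_b <- (params$m_b - config$t_start) / config$midpoint_span
  mt_d <- (params$m_d - config$t_start) / config$midpoint_span
  if (params$pi <= 0 || params$pi >= 1 || params$lambda_end <= 0 ||
      params$lambda_end >= 1 || mt_b <= 0 || mt_b >= 1 ||
      mt_d <= 0 || mt_d >= 1 ||
      any(c(params$psi_mu, params$sigma_c, params$phi_d, params$psi_bd,
            params$sigma_b_nu, params$sigma_d_nu, params$sigma_b_eta,
            params$sigma_d_eta, params$r_b, params$r_d) <= 0)) {
    return(-Inf)
  }
  dg <- function(x, hp) stats::dgamma(x, hp[1], rate = hp[2], log = TRUE)
  dg(params$psi_mu, pr$psi_mu) +
    dg(params$sigma_c, pr$sigma_c) +
    stats::dbeta(params$pi, pi_ab[1], pi_ab[2], log = TRUE) +
    stats::dnorm(log(params$phi_d), pr$log_phi_d[1], pr$log_phi_d[2],
                 log = TRUE) +
    dg(params$psi_bd, pr$psi_bd) +
    dg(params$sigma_b_nu, pr$sigma_nu) + dg(params$sigma_d_nu, pr$sigma_nu) +
    dg(params$sigma_b_eta, pr$sigma_eta) + dg(params$sigma_d_eta, pr$sigma_eta) +
    dg(params$r_b, pr$r) + dg(params$r_d, pr$r) +
    stats::dbeta(mt_b, pr$m_tilde[1], pr$m_tilde[2], log = TRUE) +
    stats::dbeta(mt_d, pr$m_tilde[1], pr$m_tilde[2], log = TRUE) +
    stats::dbeta(params$lambda_end, pr$lambda_end[1], pr$lambda_end[2],
                 log = TRUE) +
    .ddirichlet_log(params$a, pr$dirichlet_a)
}

#' Joint log posterior kernel
#'
#' Exact sum of every model component: parameter priors, the initial
#' population term, gamma population transitions (with the crisis-year
#' branch when configured), the latent log-intensity walks, gamma parish
#' observation terms for both observed and imputed counts, and the census
#' terms. `-Inf` from any component propagates; a `NaN` raises an error
#' naming the offending component.
#'
#' @param params Named list of time-invariant parameters: `sigma_c`,
#'   `psi_mu`, `pi`, `phi_d`, `psi_bd`, `sigma_b_nu`, `sigma_d_nu`,
#'   `sigma_b_eta`, `sigma_d_eta`, `r_b`, `r_d`, `m_b`, `m_d`, `a`
#'   (length-3 simplex) and `lambda_end`.
#' @param latent Named list of latent series: `mu` (over all years),
#'   `nu_b`, `nu_d` (event years x units), `eta_b`, `eta_d` (event
#'   years), and `b_hat`, `d_hat` (event years x units; values required
#'   at cells without records, other cells ignored).
#' @param data An `observed_data` object.
#' @param config A [model_config()] matching the data's span and units.
#' @return Scalar log density (possibly `-Inf`).
#' @export
joint_logpdf <- function(params, latent, data, config) {
  stopifnot(inherits(data, "observed_data"), inherits(config, "pop_model_config"))
  T_all <- length(config$years)
  T_e <- length(config$event_years)
  p <- data$n_units_included
  stopifnot(length(latent$mu) == T_all,
            nrow(latent$nu_b) == T_e, ncol(latent$nu_b) == p,
            all(dim(latent$nu_d) == c(T_e, p)),
            length(latent$eta_b) == T_e, length(latent$eta_d) == T_e)

  comp <- function(value, name) {
    if (is.nan(value) || is.na(value)) {
      stop("NaN in joint log density component: ", name)
    }
    value
  }
  total <- comp(.prior_logpdf(params, config), "priors")
  if (!is.finite(total)) return(-Inf)

  total <- total + comp(initial_pop_logpdf(latent$mu[1],
                                           config$priors$mu_init[1],
                                           config$priors$mu_init[2]),
                        "initial_population")

  lam <- .lambda_series(params, config)
  zoff <- config$zero_offset
  b <- data$b; d <- data$d
  b[data$avail_b & b <= 0] <- zoff
  d[data$avail_d & d <= 0] <- zoff

  crisis_idx <- if (is.null(config$crisis_year)) 0L else
    match(config$crisis_year, config$event_years)

  # aggregated vitals per event year (observed + imputed, coverage-scaled)
  beta <- delta <- numeric(T_e)
  for (t in seq_len(T_e)) {
    beta[t] <- aggregate_vital(b[t, data$avail_b[t, ]],
                               latent$b_hat[t, !data$avail_b[t, ]],
                               lam$b[t])
    delta[t] <- aggregate_vital(d[t, data$avail_d[t, ]],
                                latent$d_hat[t, !data$avail_d[t, ]],
                                lam$d[t])
  }

  # population transitions
  s <- data$s
  trans <- 0
  for (t in seq_len(T_e)) {
    mu_t <- latent$mu[t + 1]
    if (!is.na(crisis_idx) && t == crisis_idx) {
      # crisis branch: mean pi * mu two years before the crisis
      shape <- params$psi_mu * params$pi * latent$mu[t - 1]
      trans <- trans + if (shape <= 0 || mu_t <= 0) -Inf else
        stats::dgamma(mu_t, shape = shape, rate = params$psi_mu, log = TRUE)
    } else {
      trans <- trans + transition_logpdf(mu_t, latent$mu[t], beta[t],
                                         delta[t], s[t], params$psi_mu)
    }
    if (!is.finite(trans)) break
  }
  total <- total + comp(trans, "transitions")
  if (!is.finite(total)) return(-Inf)

  init <- .init_sds(config)
  total <- total +
    comp(latent_walk_logpdf(latent$nu_b, latent$eta_b, params$sigma_b_nu,
                            params$sigma_b_eta, init$nu_b, init$eta),
         "latent_walk_baptisms") +
    comp(latent_walk_logpdf(latent$nu_d, latent$eta_d, params$sigma_d_nu,
                            params$sigma_d_eta, init$nu_d, init$eta),
         "latent_walk_burials")

  # parish observation terms (observed and imputed)
  obs <- 0
  for (t in seq_len(T_e)) {
    cf_d <- if (!is.na(crisis_idx) && t == crisis_idx) params$phi_d else 1
    ab <- data$avail_b[t, ]; ad <- data$avail_d[t, ]
    obs <- obs +
      sum(parish_obs_logpdf(b[t, ab], latent$nu_b[t, ab], params$psi_bd)) +
      sum(parish_obs_logpdf(latent$b_hat[t, !ab], latent$nu_b[t, !ab],
                            params$psi_bd)) +
      sum(parish_obs_logpdf(d[t, ad], latent$nu_d[t, ad], params$psi_bd,
                            cf_d)) +
      sum(parish_obs_logpdf(latent$d_hat[t, !ad], latent$nu_d[t, !ad],
                            params$psi_bd, cf_d))
  }
  total <- total + comp(obs, "parish_observations")
  if (!is.finite(total)) return(-Inf)

  # census terms
  if (length(data$C)) {
    idx <- match(as.integer(names(data$C)), config$years)
    if (anyNA(idx)) stop("census year outside the model span")
    total <- total + comp(sum(census_logpdf(data$C, latent$mu[idx],
                                            params$sigma_c)),
                          "censuses")
  }
  total
}
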