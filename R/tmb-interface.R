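# Bridge between observed_data/model_config and the compiled joint
# posterior: data/parameter assembly, feasible initialisation on the
# cumulative-sum skeleton, and the map between natural parameter names
# and unconstrained sampling coordinates.

.logit <- function(x) log(x) - log1p(-x)

# Natural scalar name -> unconstrained parameter name and transform.
.scalar_transforms <- function() {
  list(
    sigma_c     = list(par = "t_log_sigma_c",     to = log),
    psi_mu      = list(par = "t_log_psi_mu",      to = log),
    pi          = list(par = "t_logit_pi",        to = .logit),
    phi_d       = list(par = "log_phi_d",         to = log),
    psi_bd      = list(par = "t_log_psi_bd",      to = log),
    sigma_b_nu  = list(par = "t_log_sigma_b_nu",  to = log),
    sigma_d_nu  = list(par = "t_log_sigma_d_nu",  to = log),
    sigma_b_eta = list(par = "t_log_sigma_b_eta", to = log),
    sigma_d_eta = list(par = "t_log_sigma_d_eta", to = log),
    r_b         = list(par = "t_log_r_b",         to = function(x) log(x - 1e-6)),
    r_d         = list(par = "t_log_r_d",         to = function(x) log(x - 1e-6)),
    lambda_end  = list(par = "t_logit_lam_end",   to = .logit)
  )
}

# Stick-breaking coordinates for a 3-simplex (inverse of the transform in
# the compiled objective).
.stick_from_a <- function(a) {
  z1 <- a[1]
  z2 <- a[2] / (1 - a[1])
  c(.logit(z1) + log(2), .logit(z2))
}

.check_span <- function(data, config) {
  if (!identical(as.integer(data$event_years),
                 as.integer(config$event_years))) {
    stop("data and config disagree on the event-year span")
  }
  if (data$n_units_included != config$n_units_included) {
    stop("data has ", data$n_units_included, " units but config expects ",
         config$n_units_included)
  }
}

# TMB data list. Observed zeros are offset here, once.
.tmb_data <- function(data, config) {
  .check_span(data, config)
  pr <- config$priors
  init <- .init_sds(config)
  b <- data$b; d <- data$d
  b[!data$avail_b] <- 0; d[!data$avail_d] <- 0
  b[data$avail_b & b <= 0] <- config$zero_offset
  d[data$avail_d & d <= 0] <- config$zero_offset
  crisis_e <- if (is.null(config$crisis_year)) -1L else
    match(config$crisis_year, config$event_years) - 1L
  census_years <- as.integer(names(data$C))
  list(
    b_obs = unname(b), d_obs = unname(d),
    avail_b = unname(data$avail_b * 1), avail_d = unname(data$avail_d * 1),
    s = unname(data$s),
    census_idx = match(census_years, config$years) - 1L,
    census_val = unname(data$C),
    crisis_e = crisis_e,
    years_e = as.numeric(config$event_years),
    t_start = as.numeric(config$t_start),
    midpoint_span = as.numeric(config$midpoint_span),
    nmiss_b = rowSums(!data$avail_b), nmiss_d = rowSums(!data$avail_d),
    pr_psi_mu = pr$psi_mu, pr_sigma_c = pr$sigma_c,
    pr_pi = unname(beta_from_mean_precision(pr$pi_mean, pr$pi_precision)),
    pr_log_phi_d = pr$log_phi_d, pr_psi_bd = pr$psi_bd,
    pr_sigma_nu = pr$sigma_nu, pr_sigma_eta = pr$sigma_eta,
    pr_r = pr$r, pr_m_tilde = pr$m_tilde, pr_lambda_end = pr$lambda_end,
    pr_dir = pr$dirichlet_a, pr_mu_init = pr$mu_init,
    init_nu_b = init$nu_b, init_nu_d = init$nu_d, init_eta = init$eta
  )
}

#' Cumulative-sum population skeleton
#'
#' Deterministic accounting path `mu_t = mu_(t-1) + B_t - D_t - s_t`
#' built from coverage-scaled register totals and anchored at the first
#' census (or at the initial-population prior mean when no census is
#' available). Used to initialise the sampler and as the reference path
#' of the noise-free accounting limit.
#'
#' @param data An `observed_data` object.
#' @param config A [model_config()].
#' @param lambda_b,lambda_d Optional coverage series over the event years
#'   (default 1, i.e. raw register totals).
#' @param impute Per-year additions standing in for missing units
#'   (default 0).
#' @return Numeric vector over `config$years`.
#' @export
accounting_skeleton <- function(data, config, lambda_b = 1, lambda_d = 1,
                                impute = list(b = 0, d = 0)) {
  .check_span(data, config)
  T_e <- length(config$event_years)
  obs_b <- rowSums(data$b * data$avail_b, na.rm = TRUE)
  obs_d <- rowSums(data$d * data$avail_d, na.rm = TRUE)
  beta <- (obs_b + rep(impute$b, length.out = T_e)) / rep(lambda_b, length.out = T_e)
  delta <- (obs_d + rep(impute$d, length.out = T_e)) / rep(lambda_d, length.out = T_e)
  inc <- beta - delta - data$s
  # crisis-year increment from the survival ratio rather than registers
  if (!is.null(config$crisis_year)) {
    ci <- match(config$crisis_year, config$event_years)
    inc[ci] <- NA  # filled after anchoring
  }
  mu <- numeric(length(config$years))
  if (length(data$C)) {
    anchor_year <- as.integer(names(data$C))[1]
    anchor_idx <- match(anchor_year, config$years)
    anchor_val <- data$C[[1]]
  } else {
    anchor_idx <- 1L
    anchor_val <- config$priors$mu_init[1] / config$priors$mu_init[2]
  }
  mu[anchor_idx] <- anchor_val
  ci <- if (is.null(config$crisis_year)) 0L else
    match(config$crisis_year, config$years)
  pi0 <- config$priors$pi_mean
  # mu[j] relates to mu[j-1] through the transition with event index j-1
  if (anchor_idx < length(mu)) {
    for (i in (anchor_idx + 1L):length(mu)) {
      mu[i] <- if (i == ci) pi0 * mu[i - 2] else mu[i - 1] + inc[i - 1L]
      if (mu[i] <= 0) mu[i] <- 0.05 * anchor_val
    }
  }
  if (anchor_idx > 1L) {
    for (i in (anchor_idx - 1L):1L) {
      mu[i] <- if (i + 1L == ci) mu[i + 1] / pi0 else mu[i + 1] - inc[i]
      if (mu[i] <= 0) mu[i] <- 0.05 * anchor_val
    }
  }
  stats::setNames(mu, config$years)
}

# Smoothed log-count initialisation for the latent intensities: observed
# cells at log(count), gaps filled by within-unit interpolation, units
# without any record at the prior initial mean.
.nu_init <- function(counts, avail, fallback) {
  T_e <- nrow(counts)
  out <- matrix(fallback, T_e, ncol(counts))
  for (i in seq_len(ncol(counts))) {
    obs <- which(avail[, i])
    if (length(obs) == 0L) next
    v <- log(pmax(counts[obs, i], 1))
    out[, i] <- if (length(obs) == 1L) v else
      stats::approx(obs, v, xout = seq_len(T_e), rule = 2)$y
  }
  out
}

# Invert the non-centred walk construction: standardised innovations
# that reproduce a target intensity field at drift zero.
.z_from_nu <- function(nu, init, sigma) {
  z <- nu
  z[1, ] <- (nu[1, ] - init[1]) / init[2]
  if (nrow(nu) > 1) {
    z[-1, ] <- (nu[-1, , drop = FALSE] - nu[-nrow(nu), , drop = FALSE]) / sigma
  }
  z
}

# Initial parameter list on sampling coordinates: cumulative-sum skeleton
# for mu, smoothed log counts for the latent walks, prior-scale values
# for scalars.
.tmb_init <- function(data, config) {
  T_e <- length(config$event_years)
  T_all <- length(config$years)
  p <- config$n_units_included
  pr <- config$priors
  init <- .init_sds(config)

  lam_end0 <- pr$lambda_end[1] / sum(pr$lambda_end)
  a0 <- pr$dirichlet_a / sum(pr$dirichlet_a)
  scal0 <- list(
    sigma_c = max(stats::sd(data$C), pr$sigma_c[1] / pr$sigma_c[2] / 10,
                  na.rm = TRUE),
    psi_mu = pr$psi_mu[1] / pr$psi_mu[2],
    pi = pr$pi_mean, phi_d = exp(pr$log_phi_d[1]),
    psi_bd = pr$psi_bd[1] / pr$psi_bd[2],
    sigma_b_nu = pr$sigma_nu[1] / pr$sigma_nu[2],
    sigma_d_nu = pr$sigma_nu[1] / pr$sigma_nu[2],
    sigma_b_eta = pr$sigma_eta[1] / pr$sigma_eta[2],
    sigma_d_eta = pr$sigma_eta[1] / pr$sigma_eta[2],
    r_b = pr$r[1] / pr$r[2], r_d = pr$r[1] / pr$r[2],
    lambda_end = lam_end0
  )
  tf <- .scalar_transforms()

  # coverage at the init point, for the skeleton's register scaling
  m0 <- config$t_start + config$midpoint_span * 0.5
  lam_b0 <- lambda_curve(scal0$r_b, m0, (a0[1] + a0[2]) * lam_end0,
                         lam_end0, config$event_years)
  lam_d0 <- lambda_curve(scal0$r_d, m0, a0[1] * lam_end0, lam_end0,
                         config$event_years)
  imp_b <- rowSums(!data$avail_b) * exp(init$nu_b[1])
  imp_d <- rowSums(!data$avail_d) * exp(init$nu_d[1])
  skel <- accounting_skeleton(data, config, lam_b0, lam_d0,
                              impute = list(b = imp_b, d = imp_d))

  log_skel <- log(pmax(skel, 1))
  pars <- list(log_mu1 = log_skel[[1]],
               w_mu = unname(diff(log_skel) *
                               sqrt(scal0$psi_mu * pmax(skel[-length(skel)], 1))))
  for (nm in names(tf)) pars[[tf[[nm]]$par]] <- tf[[nm]]$to(scal0[[nm]])
  pars$t_logit_mt_b <- 0
  pars$t_logit_mt_d <- 0
  pars$t_stick <- .stick_from_a(a0)
  nu_b0 <- .nu_init(data$b, data$avail_b, init$nu_b[1])
  nu_d0 <- .nu_init(data$d, data$avail_d, init$nu_d[1])
  pars$z_nu_b <- .z_from_nu(nu_b0, init$nu_b, scal0$sigma_b_nu)
  pars$z_nu_d <- .z_from_nu(nu_d0, init$nu_d, scal0$sigma_d_nu)
  pars$eta_b <- rep(0, T_e)
  pars$eta_d <- rep(0, T_e)
  pars$log_sb <- log(pmax(imp_b, 0.5))
  pars$log_sd_ <- log(pmax(imp_d, 0.5))
  # reorder to the declaration order of the compiled objective
  pars[c("log_mu1", "w_mu", "t_log_sigma_c", "t_log_psi_mu", "t_logit_pi",
         "log_phi_d", "t_log_psi_bd", "t_log_sigma_b_nu",
         "t_log_sigma_d_nu", "t_log_sigma_b_eta", "t_log_sigma_d_eta",
         "t_log_r_b", "t_log_r_d", "t_logit_mt_b", "t_logit_mt_d",
         "t_logit_lam_end", "t_stick", "z_nu_b", "z_nu_d", "eta_b",
         "eta_d", "log_sb", "log_sd_")]
}

# Build the TMB objective. `fixed` is a named list of natural-scale
# values to hold constant (via TMB's map mechanism), e.g.
# list(sigma_c = 30, lambda_end = 1, a = c(.5, .5, 0)).
.make_objective <- function(data, config, fixed = list()) {
  tmb_data <- .tmb_data(data, config)
  pars <- .tmb_init(data, config)
  tf <- .scalar_transforms()
  map <- list()
  for (nm in names(fixed)) {
    if (nm %in% names(tf)) {
      pars[[tf[[nm]]$par]] <- tf[[nm]]$to(fixed[[nm]])
      map[[tf[[nm]]$par]] <- factor(NA)
    } else if (nm == "a") {
      pars$t_stick <- .stick_from_a(fixed$a)
      map$t_stick <- factor(c(NA, NA))
    } else if (nm %in% c("m_b", "m_d")) {
      mt <- (fixed[[nm]] - config$t_start) / config$midpoint_span
      par <- paste0("t_logit_mt_", substr(nm, 3, 3))
      pars[[par]] <- .logit(mt)
      map[[par]] <- factor(NA)
    } else {
      stop("cannot fix unknown parameter: ", nm)
    }
  }
  # placeholders for years with no missing units never enter the model
  if (all(tmb_data$nmiss_b < 0.5) && all(tmb_data$nmiss_d < 0.5)) {
    map$log_sb <- factor(rep(NA, length(pars$log_sb)))
    map$log_sd_ <- factor(rep(NA, length(pars$log_sd_)))
  }
  obj <- TMB::MakeADFun(data = tmb_data, parameters = pars, map = map,
                        DLL = "popreconstruct", silent = TRUE)
  # the hand-fused C++ evaluator only understands the full parameter
  # vector; map-constrained fits fall back to the taped objective
  attr(obj, "tmb_data") <- tmb_data
  attr(obj, "has_map") <- length(map) > 0L
  obj
}
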