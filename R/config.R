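#' Model configuration
#'
#' Collects the study span, crisis-year handling, register coverage setup
#' and every prior hyperparameter of the hierarchical population model.
#' Defaults reproduce the historical Finnish setup: a population series
#' over 1647--1850, vital events from 1648, a famine crisis in 1697 whose
#' survival ratio compares 1697 against 1695, 177 of 197 statistical units
#' included, and the logistic-coverage midpoint scaled over 1647--1830.
#'
#' All gamma priors are shape--rate. `log_phi_d` is the (mean, sd) of the
#' log of the crisis death-inflation factor. `init_spread_is_sd` controls
#' whether the second argument of the latent-walk initial distributions
#' N(3.8, 0.5), N(3.2, 0.5) and N(0, 0.01) is read as an SD (default) or
#' as a variance.
#'
#' @param t_start,t_end First and last year of the population series.
#' @param census_years Integer years carrying a census benchmark.
#' @param crisis_year Calendar year of the mortality crisis, or `NULL` for
#'   no crisis branch. The survival ratio compares `crisis_year` with
#'   `crisis_year - 2`.
#' @param n_units_included Number of statistical units entering the
#'   likelihood (p).
#' @param n_units_total Total number of statistical units the coverage
#'   coefficient accounts for.
#' @param midpoint_span Number of years over which the scaled logistic
#'   midpoint maps onto (0, 1): `m = t_start + midpoint_span * m_tilde`.
#'   The historical default is 1830 - 1647 = 183.
#' @param zero_offset Positive value substituted for observed zero counts
#'   before they enter the continuous gamma likelihood.
#' @param init_spread_is_sd Interpret latent-walk initial spreads as SDs
#'   (`TRUE`, default) rather than variances.
#' @param priors Named list overriding individual prior hyperparameters;
#'   see Details for names and defaults.
#' @return A list of class `pop_model_config`.
#' @export
model_config <- function(t_start = 1647L, t_end = 1850L,
                         census_years = c(1749, seq(1751, 1772, by = 3),
                                          1775, 1780, seq(1800, 1850, by = 5)),
                         crisis_year = 1697L,
                         n_units_included = 177L, n_units_total = 197L,
                         midpoint_span = 183L,
                         zero_offset = 0.1,
                         init_spread_is_sd = TRUE,
                         priors = list()) {
  t_start <- as.integer(t_start); t_end <- as.integer(t_end)
  stopifnot(t_end > t_start + 2L)
  census_years <- sort(unique(as.integer(census_years)))
  if (length(census_years) &&
      (min(census_years) <= t_start || max(census_years) > t_end)) {
    stop("census years must lie within (t_start, t_end]")
  }
  if (!is.null(crisis_year)) {
    crisis_year <- as.integer(crisis_year)
    if (crisis_year < t_start + 2L || crisis_year > t_end) {
      stop("crisis_year must allow a comparison with crisis_year - 2 ",
           "inside the span")
    }
  }
  p <- as.integer(n_units_included); ntot <- as.integer(n_units_total)
  stopifnot(p >= 1L, ntot >= p)
  default_priors <- list(
    psi_mu     = c(2, 4),
    sigma_c    = c(1, 1e-4),
    pi_mean    = 0.775,
    pi_precision = 200,
    log_phi_d  = c(2, 0.25),
    psi_bd     = c(2, 4),
    sigma_nu   = c(2, 10),
    sigma_eta  = c(2, 20),
    r          = c(2, 20),
    m_tilde    = c(5, 5),
    # floor keeps the prior proper when every unit is included (p = total)
    lambda_end = c(10 * p / ntot, max(10 * (1 - p / ntot), 0.5)),
    dirichlet_a = c(10, 5, 5),
    mu_init    = c(215, 5e-4),
    nu_b_init  = c(3.8, 0.5),
    nu_d_init  = c(3.2, 0.5),
    eta_init   = c(0, 0.01)
  )
  unknown <- setdiff(names(priors), names(default_priors))
  if (length(unknown)) stop("unknown prior names: ", paste(unknown, collapse = ", "))
  default_priors[names(priors)] <- priors
  structure(list(
    t_start = t_start, t_end = t_end,
    years = t_start:t_end,
    event_years = (t_start + 1L):t_end,
    census_years = census_years,
    crisis_year = crisis_year,
    n_units_included = p, n_units_total = ntot,
    midpoint_span = as.integer(midpoint_span),
    zero_offset = zero_offset,
    init_spread_is_sd = isTRUE(init_spread_is_sd),
    priors = default_priors
  ), class = "pop_model_config")
}

#' @export
print.pop_model_config <- function(x, ...) {
  cat("Population model configuration\n")
  cat("  span          :", x$t_start, "-", x$t_end,
      sprintf("(%d years, events from %d)\n", length(x$years), x$event_years[1]))
  cat("  census years  :", length(x$census_years), "\n")
  cat("  crisis year   :",
      if (is.null(x$crisis_year)) "none" else x$crisis_year, "\n")
  cat("  units         :", x$n_units_included, "of", x$n_units_total, "\n")
  invisible(x)
}

# Latent-walk initial spreads on the SD scale, honouring the SD/variance
# switch.
.init_sds <- function(config) {
  f <- if (config$init_spread_is_sd) identity else sqrt
  list(nu_b = c(config$priors$nu_b_init[1], f(config$priors$nu_b_init[2])),
       nu_d = c(config$priors$nu_d_init[1], f(config$priors$nu_d_init[2])),
       eta  = c(config$priors$eta_init[1],  f(config$priors$eta_init[2])))
}
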