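# Derived demographic quantities and posterior predictive checks. All
# statistics are draw-wise functionals of the population path, summarised
# afterwards -- never functions of an already-summarised series.

.mu_draws <- function(fit) {
  if (inherits(fit, "pop_fit")) fit$mu else as.matrix(fit)
}

.year_idx <- function(mu, year) {
  idx <- match(as.character(year), colnames(mu))
  if (anyNA(idx)) stop("year(s) outside the fitted span: ",
                       paste(year[is.na(idx)], collapse = ", "))
  idx
}

#' Annual population summary
#'
#' Posterior mean and central 95% interval of the population for every
#' year.
#'
#' @param fit A `pop_fit` (or a draws x years matrix with year column
#'   names).
#' @return Data frame with columns `year`, `mean`, `q2.5`, `q97.5`.
#' @export
population_summary <- function(fit) {
  mu <- .mu_draws(fit)
  data.frame(
    year = as.integer(colnames(mu)),
    mean = colMeans(mu),
    q2.5 = apply(mu, 2, stats::quantile, 0.025),
    q97.5 = apply(mu, 2, stats::quantile, 0.975),
    row.names = NULL
  )
}

#' Posterior probabilities of average annual growth-rate categories
#'
#' For each posterior draw the average annual growth over the period is
#' the geometric (compound) rate
#' `g = (mu_end / mu_start)^(1 / (end - start)) - 1`; draws are then
#' binned at the cutpoints and the bin fractions reported. An arithmetic
#' definition (mean of yearly growth rates) is also available.
#'
#' @param fit A `pop_fit` or draws x years matrix.
#' @param period Length-2 integer vector `(start, end)` years.
#' @param cutpoints Increasing growth-rate cutpoints (per year, e.g.
#'   `c(0, 0.005)`).
#' @param method `"geometric"` (default) or `"arithmetic"`.
#' @return Named vector of bin probabilities (summing to 1), named by the
#'   bin bounds.
#' @export
growth_rate_probabilities <- function(fit, period, cutpoints,
                                      method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  mu <- .mu_draws(fit)
  if (is.unsorted(cutpoints, strictly = TRUE)) {
    stop("cutpoints must be strictly increasing")
  }
  idx <- .year_idx(mu, period)
  nyr <- diff(period)
  g <- if (method == "geometric") {
    (mu[, idx[2]] / mu[, idx[1]])^(1 / nyr) - 1
  } else {
    span <- idx[1]:idx[2]
    rowMeans(mu[, span[-1], drop = FALSE] /
               mu[, span[-length(span)], drop = FALSE] - 1)
  }
  breaks <- c(-Inf, cutpoints, Inf)
  tab <- table(cut(g, breaks = breaks, right = FALSE))
  stats::setNames(as.numeric(tab) / length(g), names(tab))
}

#' Posterior drop magnitude between two years
#'
#' Per-draw relative decline `1 - mu[year_lo] / mu[year_hi]`, summarised
#' by its posterior mean and central 95% interval.
#'
#' @param fit A `pop_fit` or draws x years matrix.
#' @param year_hi,year_lo Years being compared (e.g. 1696 and 1697).
#' @return List with `mean`, `q2.5`, `q97.5`, and the per-draw vector
#'   `draws`.
#' @export
drop_magnitude <- function(fit, year_hi, year_lo) {
  mu <- .mu_draws(fit)
  idx <- .year_idx(mu, c(year_hi, year_lo))
  d <- 1 - mu[, idx[2]] / mu[, idx[1]]
  list(mean = mean(d),
       q2.5 = unname(stats::quantile(d, 0.025)),
       q97.5 = unname(stats::quantile(d, 0.975)),
       draws = d)
}

#' Posterior peak/trough years and maximum-drop magnitude
#'
#' Per draw: the argmax (peak) or argmin (trough) year within the range
#' (ties broken to the earliest year) and the max-minus-min magnitude.
#' Reports the posterior distribution over years, the posterior median
#' year, and the mean and central 95% interval of the magnitude.
#'
#' @param fit A `pop_fit` or draws x years matrix.
#' @param range Length-2 integer vector of years delimiting the search.
#' @param mode `"peak"` or `"trough"`.
#' @return List with `year_distribution` (named fractions),
#'   `median_year`, `magnitude_mean`, `magnitude_q2.5`,
#'   `magnitude_q97.5`, and per-draw vectors `years` and `magnitudes`.
#' @export
extremum_years <- function(fit, range, mode = c("peak", "trough")) {
  mode <- match.arg(mode)
  mu <- .mu_draws(fit)
  idx <- .year_idx(mu, range)
  sub <- mu[, idx[1]:idx[2], drop = FALSE]
  years <- as.integer(colnames(sub))
  pick <- if (mode == "peak") max.col(sub, ties.method = "first") else
    max.col(-sub, ties.method = "first")
  yr <- years[pick]
  mag <- apply(sub, 1, max) - apply(sub, 1, min)
  list(
    year_distribution = table(factor(yr, levels = years)) / length(yr),
    median_year = stats::median(yr),
    magnitude_mean = mean(mag),
    magnitude_q2.5 = unname(stats::quantile(mag, 0.025)),
    magnitude_q97.5 = unname(stats::quantile(mag, 0.975)),
    years = yr, magnitudes = mag
  )
}

#' First year the population re-attains a reference level
#'
#' Per draw, the first year strictly after `reference_year` whose
#' population is at least the population of `reference_year` in that
#' draw; draws that never return are censored.
#'
#' @param fit A `pop_fit` or draws x years matrix.
#' @param reference_year Integer year.
#' @return List with `median_year`, `q2.5`, `q97.5` (over returning
#'   draws), `prop_censored`, and the per-draw `years` (NA = censored).
#' @export
first_return_year <- function(fit, reference_year) {
  mu <- .mu_draws(fit)
  ref <- .year_idx(mu, reference_year)
  years <- as.integer(colnames(mu))
  later <- mu[, (ref + 1):ncol(mu), drop = FALSE] >= mu[, ref]
  hit <- apply(later, 1, function(z) {
    w <- which(z)
    if (length(w)) w[1] else NA_integer_
  })
  yr <- years[ref + hit]
  ok <- !is.na(yr)
  list(median_year = if (any(ok)) stats::median(yr[ok]) else NA,
       q2.5 = if (any(ok)) unname(stats::quantile(yr[ok], 0.025)) else NA,
       q97.5 = if (any(ok)) unname(stats::quantile(yr[ok], 0.975)) else NA,
       prop_censored = mean(!ok),
       years = yr)
}

#' Posterior predictive replication of the population path and censuses
#'
#' For each selected posterior draw, regenerates the aggregated vitals
#' treating every parish record as missing (new gamma count draws from
#' the posterior latent intensities), propagates a new population path
#' through the gamma transitions (crisis branch included), and samples
#' hypothetical censuses from the census noise model. Replications whose
#' regenerated path becomes infeasible are resampled up to `max_retry`
#' times, then counted as failed.
#'
#' @param fit A `pop_fit` with stored latent intensities.
#' @param n_rep Number of replications (default 1000, capped at the
#'   number of available draws with resampling allowed).
#' @param seed Integer seed.
#' @param max_retry Resampling cap per replication (default 100).
#' @return List with `mu_rep` (replications x years), `census_rep`
#'   (replications x census years), `draw_ids`, and `n_failed`.
#' @export
posterior_predictive <- function(fit, n_rep = 1000L, seed = 1L,
                                 max_retry = 100L) {
  stopifnot(inherits(fit, "pop_fit"))
  if (is.null(fit$nu_b)) stop("fit was run with store_latent = FALSE")
  set.seed(as.integer(seed))
  cfg <- fit$config
  T_e <- length(cfg$event_years)
  T_all <- length(cfg$years)
  p <- cfg$n_units_included
  crisis_e <- if (is.null(cfg$crisis_year)) 0L else
    match(cfg$crisis_year, cfg$event_years)
  n_avail <- nrow(fit$params)
  draw_ids <- sample.int(n_avail, n_rep, replace = n_rep > n_avail)

  mu_rep <- matrix(NA_real_, n_rep, T_all,
                   dimnames = list(NULL, cfg$years))
  census_rep <- matrix(NA_real_, n_rep, length(cfg$census_years),
                       dimnames = list(NULL, cfg$census_years))
  cens_idx <- match(cfg$census_years, cfg$years)
  n_failed <- 0L

  for (j in seq_len(n_rep)) {
    k <- draw_ids[j]
    psi_bd <- fit$params$psi_bd[k]
    psi_mu <- fit$params$psi_mu[k]
    pi_k <- fit$params$pi[k]
    phi_d <- fit$params$phi_d[k]
    shapes_b <- psi_bd * exp(fit$nu_b[k, , ])
    shapes_d <- psi_bd * exp(fit$nu_d[k, , ])
    if (crisis_e > 0) shapes_d[crisis_e, ] <- shapes_d[crisis_e, ] * phi_d
    ok <- FALSE
    for (attempt in seq_len(max_retry)) {
      B <- matrix(stats::rgamma(T_e * p, shape = shapes_b, rate = psi_bd),
                  T_e, p)
      D <- matrix(stats::rgamma(T_e * p, shape = shapes_d, rate = psi_bd),
                  T_e, p)
      beta <- rowSums(B) / fit$lambda_b[k, ]
      delta <- rowSums(D) / fit$lambda_d[k, ]
      mu <- numeric(T_all)
      mu[1] <- fit$mu[k, 1]
      feasible <- TRUE
      for (t in seq_len(T_e)) {
        mean_t <- if (t == crisis_e) pi_k * mu[t - 1] else
          mu[t] + beta[t] - delta[t] - fit$data$s[t]
        if (mean_t <= 0) { feasible <- FALSE; break }
        mu[t + 1] <- stats::rgamma(1, shape = psi_mu * mean_t,
                                   rate = psi_mu)
      }
      if (feasible) { ok <- TRUE; break }
    }
    if (!ok) { n_failed <- n_failed + 1L; next }
    mu_rep[j, ] <- mu
    census_rep[j, ] <- stats::rnorm(length(cens_idx), mu[cens_idx],
                                    fit$params$sigma_c[k])
  }
  list(mu_rep = mu_rep, census_rep = census_rep, draw_ids = draw_ids,
       n_failed = n_failed)
}
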