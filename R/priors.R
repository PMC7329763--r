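#' Prior specification
#'
#' Constructs a validated prior specification for one of the distribution
#' families used by the population model. Gamma distributions are always
#' shape--rate; `"normal-sd"` takes a standard deviation (not a variance);
#' `"beta-mean-precision"` is the mean/precision parameterisation with
#' `alpha = mean * precision`, `beta = (1 - mean) * precision`;
#' `"lognormal"` takes the mean and SD of the log.
#'
#' @param family One of `"gamma-shape-rate"`, `"normal-sd"`, `"beta-ab"`,
#'   `"beta-mean-precision"`, `"dirichlet"`, `"lognormal"`.
#' @param ... Numeric parameters, in the family's natural order:
#'   `(shape, rate)`, `(mean, sd)`, `(alpha, beta)`, `(mean, precision)`,
#'   `(w1, w2, ...)`, `(meanlog, sdlog)`.
#' @return An object of class `prior_spec`.
#' @examples
#' prior_spec("gamma-shape-rate", 2, 4)
#' prior_spec("beta-mean-precision", 0.775, 200)
#' @export
prior_spec <- function(family = c("gamma-shape-rate", "normal-sd", "beta-ab",
                                  "beta-mean-precision", "dirichlet",
                                  "lognormal"), ...) {
  family <- match.arg(family)
  pars <- unlist(list(...), use.names = FALSE)
  if (!is.numeric(pars) || anyNA(pars)) {
    stop("prior parameters must be numeric and non-missing")
  }
  check <- switch(family,
    "gamma-shape-rate" = length(pars) == 2 && all(pars > 0),
    "normal-sd"        = length(pars) == 2 && pars[2] > 0,
    "beta-ab"          = length(pars) == 2 && all(pars > 0),
    "beta-mean-precision" = length(pars) == 2 &&
      pars[1] > 0 && pars[1] < 1 && pars[2] > 0,
    "dirichlet"        = length(pars) >= 2 && all(pars > 0),
    "lognormal"        = length(pars) == 2 && pars[2] > 0
  )
  if (!check) {
    stop("invalid parameters for family '", family, "': ",
         paste(pars, collapse = ", "))
  }
  structure(list(family = family, parameters = pars), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(x$family, "(", paste(format(x$parameters), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Convert a mean/precision beta prior to shape parameters
#'
#' @param mean Prior mean in (0, 1).
#' @param precision Prior precision (alpha + beta), positive.
#' @return Named numeric vector `c(alpha, beta)`.
#' @examples
#' beta_from_mean_precision(0.775, 200) # c(155, 45)
#' @export
beta_from_mean_precision <- function(mean, precision) {
  stopifnot(is.numeric(mean), is.numeric(precision))
  if (mean <= 0 || mean >= 1) stop("mean must lie strictly in (0, 1)")
  if (precision <= 0) stop("precision must be positive")
  c(alpha = mean * precision, beta = (1 - mean) * precision)
}

# Reduce a prior_spec to the effective (family, parameters) used by the
# quantile/moment routines: mean-precision betas become beta-ab.
.canonical_spec <- function(spec) {
  stopifnot(inherits(spec, "prior_spec"))
  if (spec$family == "beta-mean-precision") {
    ab <- beta_from_mean_precision(spec$parameters[1], spec$parameters[2])
    list(family = "beta-ab", parameters = unname(ab))
  } else {
    list(family = spec$family, parameters = spec$parameters)
  }
}

#' Exact quantile of a prior
#'
#' Dirichlet specs have no scalar quantile; aggregate a component with
#' [dirichlet_marginal()] first.
#'
#' @param spec A [prior_spec()].
#' @param q Probabilities in (0, 1); vectorised.
#' @return Quantiles on the distribution's natural scale.
#' @examples
#' prior_quantile(prior_spec("gamma-shape-rate", 1, 1e-4), c(0.025, 0.975))
#' @export
prior_quantile <- function(spec, q) {
  if (any(q <= 0) || any(q >= 1)) stop("q must lie strictly in (0, 1)")
  s <- .canonical_spec(spec)
  p <- s$parameters
  switch(s$family,
    "gamma-shape-rate" = stats::qgamma(q, shape = p[1], rate = p[2]),
    "normal-sd"        = stats::qnorm(q, mean = p[1], sd = p[2]),
    "beta-ab"          = stats::qbeta(q, p[1], p[2]),
    "lognormal"        = stats::qlnorm(q, meanlog = p[1], sdlog = p[2]),
    "dirichlet"        = stop("Dirichlet has no scalar quantile; ",
                              "use dirichlet_marginal() first")
  )
}

#' CDF of a prior (inverse of [prior_quantile()])
#' @inheritParams prior_quantile
#' @param x Values on the distribution's natural scale.
#' @export
prior_cdf <- function(spec, x) {
  s <- .canonical_spec(spec)
  p <- s$parameters
  switch(s$family,
    "gamma-shape-rate" = stats::pgamma(x, shape = p[1], rate = p[2]),
    "normal-sd"        = stats::pnorm(x, mean = p[1], sd = p[2]),
    "beta-ab"          = stats::pbeta(x, p[1], p[2]),
    "lognormal"        = stats::plnorm(x, meanlog = p[1], sdlog = p[2]),
    "dirichlet"        = stop("Dirichlet has no scalar CDF; ",
                              "use dirichlet_marginal() first")
  )
}

#' Marginal (aggregated) component of a Dirichlet prior
#'
#' By the aggregation property of the Dirichlet distribution, the sum of a
#' subset S of components is Beta(sum of weights in S, sum of the rest).
#'
#' @param weights Positive Dirichlet concentration weights.
#' @param index_set Integer indices of the components to aggregate; must be
#'   a non-empty proper subset.
#' @return A beta [prior_spec()] for the aggregated component.
#' @examples
#' dirichlet_marginal(c(10, 5, 5), 1)    # Beta(10, 10)
#' dirichlet_marginal(c(10, 5, 5), 1:2)  # Beta(15, 5)
#' @export
dirichlet_marginal <- function(weights, index_set) {
  if (any(weights <= 0)) stop("Dirichlet weights must be positive")
  k <- length(weights)
  index_set <- unique(as.integer(index_set))
  if (length(index_set) == 0 || length(index_set) >= k ||
      any(index_set < 1) || any(index_set > k)) {
    stop("index_set must be a non-empty proper subset of 1..", k)
  }
  prior_spec("beta-ab", sum(weights[index_set]), sum(weights[-index_set]))
}

#' Exact mean and standard deviation of a prior
#'
#' @param spec A [prior_spec()]. For Dirichlet specs the componentwise
#'   means and SDs are returned.
#' @return Named list with `mean` and `sd`.
#' @examples
#' prior_moments(prior_spec("gamma-shape-rate", 215, 5e-4)) # mean 430000
#' @export
prior_moments <- function(spec) {
  s <- .canonical_spec(spec)
  p <- s$parameters
  switch(s$family,
    "gamma-shape-rate" = list(mean = p[1] / p[2], sd = sqrt(p[1]) / p[2]),
    "normal-sd"        = list(mean = p[1], sd = p[2]),
    "beta-ab"          = {
      m <- p[1] / (p[1] + p[2])
      v <- p[1] * p[2] / ((p[1] + p[2])^2 * (p[1] + p[2] + 1))
      list(mean = m, sd = sqrt(v))
    },
    "lognormal"        = {
      m <- exp(p[1] + p[2]^2 / 2)
      v <- (exp(p[2]^2) - 1) * exp(2 * p[1] + p[2]^2)
      list(mean = m, sd = sqrt(v))
    },
    "dirichlet"        = {
      w0 <- sum(p)
      m <- p / w0
      v <- p * (w0 - p) / (w0^2 * (w0 + 1))
      list(mean = m, sd = sqrt(v))
    }
  )
}

#' Table of all model priors
#'
#' One row per prior in the model configuration: family, parameters, mean,
#' SD, and central 95% quantiles. Dirichlet components are listed through
#' their beta marginals. Intended for audit of the prior assumptions.
#'
#' @param config A [model_config()]; defaults to the historical setup.
#' @return A data frame.
#' @export
prior_table <- function(config = model_config()) {
  pr <- config$priors
  specs <- list(
    psi_mu      = prior_spec("gamma-shape-rate", pr$psi_mu[1], pr$psi_mu[2]),
    sigma_c     = prior_spec("gamma-shape-rate", pr$sigma_c[1], pr$sigma_c[2]),
    pi          = prior_spec("beta-mean-precision", pr$pi_mean, pr$pi_precision),
    phi_d       = prior_spec("lognormal", pr$log_phi_d[1], pr$log_phi_d[2]),
    psi_bd      = prior_spec("gamma-shape-rate", pr$psi_bd[1], pr$psi_bd[2]),
    sigma_b_nu  = prior_spec("gamma-shape-rate", pr$sigma_nu[1], pr$sigma_nu[2]),
    sigma_d_nu  = prior_spec("gamma-shape-rate", pr$sigma_nu[1], pr$sigma_nu[2]),
    sigma_b_eta = prior_spec("gamma-shape-rate", pr$sigma_eta[1], pr$sigma_eta[2]),
    sigma_d_eta = prior_spec("gamma-shape-rate", pr$sigma_eta[1], pr$sigma_eta[2]),
    r_b         = prior_spec("gamma-shape-rate", pr$r[1], pr$r[2]),
    r_d         = prior_spec("gamma-shape-rate", pr$r[1], pr$r[2]),
    m_tilde     = prior_spec("beta-ab", pr$m_tilde[1], pr$m_tilde[2]),
    lambda_end  = prior_spec("beta-ab", pr$lambda_end[1], pr$lambda_end[2]),
    a1          = dirichlet_marginal(pr$dirichlet_a, 1),
    a1_plus_a2  = dirichlet_marginal(pr$dirichlet_a, 1:2),
    mu_init     = prior_spec("gamma-shape-rate", pr$mu_init[1], pr$mu_init[2])
  )
  rows <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    mo <- prior_moments(sp)
    qs <- prior_quantile(sp, c(0.025, 0.975))
    data.frame(
      quantity = nm, family = sp$family,
      parameters = paste(format(sp$parameters, trim = TRUE), collapse = ", "),
      mean = mo$mean, sd = mo$sd, q2.5 = qs[1], q97.5 = qs[2],
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  do.call(rbind, rows)
}
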