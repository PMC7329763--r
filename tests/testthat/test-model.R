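# explicit density formulas used as oracles (kept separate from the
# implementation on purpose)
gamma_lpdf <- function(x, shape, rate) {
  shape * log(rate) - lgamma(shape) + (shape - 1) * log(x) - rate * x
}
normal_lpdf <- function(x, m, s) {
  -0.5 * log(2 * pi) - log(s) - 0.5 * ((x - m) / s)^2
}

test_that("coverage curve hits its endpoints exactly and is monotone", {
  years <- 1648:1850
  lam <- lambda_curve(0.1, 1703, 0.49, 0.85, years)
  expect_equal(lam[1], 0.49)
  expect_equal(lam[length(lam)], 0.85)
  expect_true(all(diff(lam) >= 0))
  # hand-evaluated two-point affine map of the raw logistic at t = m
  raw <- stats::plogis(0.1 * (years - 1703))
  expect_equal(lam[years == 1703],
               (0.5 - raw[1]) / (raw[length(raw)] - raw[1]) *
                 (0.85 - 0.49) + 0.49)
  expect_error(lambda_curve(1e-14, 1703, 0.49, 0.85, years), "degenerate")
})

test_that("crisis coefficient satisfies its defining identity", {
  # the plain unit case: numerator 400 + 10 - 0 - 310 = 100 over delta 100
  phi <- famine_phi_mu(400, 10, 0, pi = 310 / 400, mu_1695 = 400, 100)
  expect_equal(phi, 1)
  # algebraic oracle at realistic magnitudes
  phi2 <- famine_phi_mu(420000, 12000, 500, 0.775, 450000, 120000)
  expect_equal(phi2, (420000 + 12000 - 500 - 0.775 * 450000) / 120000)
  # substituting back recovers the target mean for random admissible states
  set.seed(1)
  for (k in 1:25) {
    mu96 <- runif(1, 2e5, 6e5); b <- runif(1, 5e3, 5e4)
    s <- runif(1, 0, 5e3); pi_ <- runif(1, 0.6, 0.9)
    mu95 <- runif(1, 2e5, 6e5); d <- runif(1, 1e4, 2e5)
    phi <- famine_phi_mu(mu96, b, s, pi_, mu95, d)
    expect_equal(mu96 + b - phi * d - s, pi_ * mu95, tolerance = 1e-9)
  }
  expect_error(famine_phi_mu(1, 1, 0, 0.5, 1, 0), "positive")
})

test_that("population transition density has gamma form with -Inf support edge", {
  expect_identical(transition_logpdf(1e5, 100, 10, 500, 0, 0.4), -Inf)
  expect_identical(transition_logpdf(-5, 1e5, 100, 50, 0, 0.4), -Inf)
  # reference pdf oracle
  v <- transition_logpdf(410000, 409000, 1000, 400, 100, 0.38)
  mean_t <- 409000 + 1000 - 400 - 100
  expect_equal(v, gamma_lpdf(410000, 0.38 * mean_t, 0.38), tolerance = 1e-10)
  # implied moments: mean and variance of the gamma
  shape <- 0.38 * mean_t
  expect_equal(shape / 0.38, mean_t)
  expect_equal(shape / 0.38^2, mean_t / 0.38)
})

test_that("initial population and census densities match reference formulas", {
  expect_equal(initial_pop_logpdf(430000),
               gamma_lpdf(430000, 215, 5e-4), tolerance = 1e-10)
  expect_identical(initial_pop_logpdf(-1), -Inf)
  expect_equal(census_logpdf(500000, 498000, 2358),
               normal_lpdf(500000, 498000, 2358), tolerance = 1e-12)
  # maximal at equality, symmetric in the residual
  expect_gt(census_logpdf(5e5, 5e5, 1000), census_logpdf(5e5 + 1, 5e5, 1000))
  expect_equal(census_logpdf(5e5 + 777, 5e5, 1000),
               census_logpdf(5e5 - 777, 5e5, 1000))
})

test_that("vital aggregation is coverage-scaled addition", {
  expect_equal(aggregate_vital(c(3, 4, 5), numeric(0), 1), 12)
  expect_equal(aggregate_vital(50, 50, 0.5), 200)
  set.seed(2)
  obs <- rgamma(7, 40); imp <- rgamma(4, 30); lam <- 0.73
  expect_equal(aggregate_vital(obs, imp, lam), (sum(obs) + sum(imp)) / lam)
  expect_error(aggregate_vital(1, 1, 0), "positive")
})

test_that("parish observation density matches the gamma reference", {
  v <- parish_obs_logpdf(55, 4.0, 0.33)
  expect_equal(v, gamma_lpdf(55, 0.33 * exp(4), 0.33), tolerance = 1e-10)
  # crisis factor multiplies the shape; factor 1 reduces to the plain form
  v2 <- parish_obs_logpdf(55, 4.0, 0.33, crisis_factor = 5.2)
  expect_equal(v2, gamma_lpdf(55, 0.33 * 5.2 * exp(4), 0.33),
               tolerance = 1e-10)
  expect_equal(parish_obs_logpdf(55, 4.0, 0.33, 1), v)
  # implied mean equals crisis_factor * exp(nu) (shape / rate)
  expect_equal(0.33 * 5.2 * exp(4) / 0.33, 5.2 * exp(4))
})

test_that("latent walk density equals a brute-force sum of normal terms", {
  nu <- matrix(c(3.8, 3.9, 4.1, 3.2, 3.3, 3.1), 3, 2)
  eta <- c(0.01, 0.02, -0.01)
  v <- latent_walk_logpdf(nu, eta, 0.09, 0.01,
                          nu_init = c(3.8, 0.5), eta_init = c(0, 0.01))
  oracle <- normal_lpdf(eta[1], 0, 0.01) +
    sum(normal_lpdf(diff(eta), 0, 0.01)) +
    sum(normal_lpdf(nu[1, ], 3.8, 0.5))
  for (t in 2:3) for (i in 1:2) {
    oracle <- oracle + normal_lpdf(nu[t, i] - nu[t - 1, i] - eta[t], 0, 0.09)
  }
  expect_equal(v, oracle, tolerance = 1e-12)
  # constant walk with zero drift: increments all contribute lpdf(0)
  nu0 <- matrix(3.5, 4, 3)
  v0 <- latent_walk_logpdf(nu0, rep(0, 4), 0.1, 0.02,
                           nu_init = c(3.5, 0.5), eta_init = c(0, 0.01))
  expect_equal(v0, normal_lpdf(0, 0, 0.01) + 3 * normal_lpdf(0, 0, 0.02) +
                 3 * normal_lpdf(0, 0, 0.5) + 9 * normal_lpdf(0, 0, 0.1),
               tolerance = 1e-12)
})

test_that("joint density is separable: a census nudge moves only the census term", {
  scen <- tiny_scenario()
  ds <- simulate_dataset(scen, 5)
  set.seed(9)
  params <- random_params(scen$config)
  latent <- random_latent(ds$data, scen$config)
  j1 <- joint_logpdf(params, latent, ds$data, scen$config)
  data2 <- ds$data
  data2$C[2] <- data2$C[2] + 1500
  j2 <- joint_logpdf(params, latent, data2, scen$config)
  yr <- as.integer(names(ds$data$C)[2])
  mu_t <- latent$mu[match(yr, scen$config$years)]
  expect_equal(j2 - j1,
               census_logpdf(data2$C[[2]], mu_t, params$sigma_c) -
                 census_logpdf(ds$data$C[[2]], mu_t, params$sigma_c),
               tolerance = 1e-8)
})

test_that("crisis transition mean equals pi times the pre-crisis population", {
  # sampling-route check: the compiled kernel and the R joint agree on
  # how a change in pi moves the crisis transition term only
  scen <- tiny_scenario()
  ds <- simulate_dataset(scen, 6)
  set.seed(10)
  params <- random_params(scen$config)
  latent <- random_latent(ds$data, scen$config)
  j1 <- joint_logpdf(params, latent, ds$data, scen$config)
  params2 <- params; params2$pi <- params$pi + 0.01
  j2 <- joint_logpdf(params2, latent, ds$data, scen$config)
  cfg <- scen$config
  ci <- match(cfg$crisis_year, cfg$event_years)
  lam <- popreconstruct:::.lambda_series(params, cfg)
  # delta at the crisis year does not enter the transition; only the
  # shape psi_mu * pi * mu_(c-2) changes with pi (plus the pi prior)
  mu_c <- latent$mu[ci + 1]
  mu_cm2 <- latent$mu[ci - 1]
  dgam <- function(pi_) stats::dgamma(mu_c, shape = params$psi_mu * pi_ * mu_cm2,
                                      rate = params$psi_mu, log = TRUE)
  ab <- beta_from_mean_precision(cfg$priors$pi_mean, cfg$priors$pi_precision)
  dpr <- function(pi_) stats::dbeta(pi_, ab[1], ab[2], log = TRUE)
  expect_equal(j2 - j1,
               dgam(params2$pi) - dgam(params$pi) +
                 dpr(params2$pi) - dpr(params$pi),
               tolerance = 1e-8)
})
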