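# a draws x years matrix with named year columns
mu_matrix <- function(draws) {
  colnames(draws) <- as.character(seq_len(ncol(draws)) + 1699L)
  draws
}

test_that("growth-rate probabilities bin compound growth and sum to one", {
  set.seed(14)
  mu <- mu_matrix(matrix(rep(1e5, 200 * 11), 200, 11))
  pr <- growth_rate_probabilities(mu, c(1700, 1710), c(0, 0.005))
  expect_equal(sum(pr), 1)
  expect_equal(unname(pr[2]), 1)  # zero growth falls in [0, 0.005)
  # closed-form binning oracle: per-draw growth is lognormal
  n_yr <- 10
  m <- 0.002 * n_yr; s <- 0.004 * sqrt(n_yr)
  L <- rnorm(5e4, m, s)
  mu2 <- mu_matrix(cbind(rep(1e5, 5e4),
                         matrix(1e5, 5e4, 9), 1e5 * exp(L)))
  pr2 <- growth_rate_probabilities(mu2, c(1700, 1710), c(0, 0.005))
  exact <- c(pnorm(0, m / n_yr, s / n_yr, lower.tail = TRUE),
             pnorm(log(1.005), m / n_yr, s / n_yr) -
               pnorm(0, m / n_yr, s / n_yr),
             pnorm(log(1.005), m / n_yr, s / n_yr, lower.tail = FALSE))
  expect_equal(unname(pr2), exact, tolerance = 0.02)
  # arithmetic variant is exposed and differs in general
  pr3 <- growth_rate_probabilities(mu2, c(1700, 1710), c(0, 0.005),
                                   method = "arithmetic")
  expect_equal(sum(pr3), 1)
})

test_that("drop magnitude is the per-draw ratio statistic", {
  mu <- mu_matrix(matrix(1e5, 50, 11))
  d0 <- drop_magnitude(mu, 1705, 1706)
  expect_equal(d0$mean, 0)
  set.seed(3)
  mu2 <- mu_matrix(matrix(runif(50 * 11, 9e4, 1.1e5), 50, 11))
  d <- drop_magnitude(mu2, 1705, 1706)
  draws <- 1 - mu2[, "1706"] / mu2[, "1705"]
  expect_equal(d$mean, mean(draws))
  expect_equal(d$q2.5, unname(quantile(draws, 0.025)))
  expect_equal(d$q97.5, unname(quantile(draws, 0.975)))
})

test_that("extremum years use per-draw argmax with earliest tie-break", {
  inc <- mu_matrix(matrix(rep(1:11, each = 20) * 1000, 20, 11))
  pk <- extremum_years(inc, c(1700, 1710), "peak")
  expect_equal(pk$median_year, 1710)
  tr <- extremum_years(inc, c(1700, 1710), "trough")
  expect_equal(tr$median_year, 1700)
  # tie: flat path picks the earliest year
  flat <- mu_matrix(matrix(5e4, 10, 11))
  expect_equal(extremum_years(flat, c(1700, 1710), "peak")$median_year, 1700)
  # magnitude equals brute-force per-draw max minus min
  set.seed(8)
  mu2 <- mu_matrix(matrix(runif(30 * 11, 1e5, 2e5), 30, 11))
  ex <- extremum_years(mu2, c(1702, 1709), "peak")
  sub <- mu2[, as.character(1702:1709)]
  expect_equal(ex$magnitudes, apply(sub, 1, max) - apply(sub, 1, min))
  expect_equal(ex$magnitude_mean, mean(ex$magnitudes))
})

test_that("derived statistics are draw-wise, not functions of the mean path", {
  # two draws peaking in different years: the mean path has a single
  # peak year, while the per-draw distribution splits its mass
  a <- c(1, 3, 1); b <- c(1, 1, 3)
  mu <- mu_matrix(rbind(a, b)[, c(1, 2, 3)] * 1e4)
  colnames(mu) <- c("1700", "1701", "1702")
  ex <- extremum_years(mu, c(1700, 1702), "peak")
  expect_equal(as.numeric(ex$year_distribution[c("1701", "1702")]),
               c(0.5, 0.5))
  mean_path_peak <- names(which.max(colMeans(mu)))
  expect_length(mean_path_peak, 1)
})

test_that("first return year handles monotone, censored and toy cases", {
  inc <- mu_matrix(matrix(rep(1:11, each = 5) * 1000, 5, 11))
  fr <- first_return_year(inc, 1703)
  expect_equal(fr$median_year, 1704)
  expect_equal(fr$prop_censored, 0)
  dec <- mu_matrix(matrix(rep(11:1, each = 5) * 1000, 5, 11))
  fr2 <- first_return_year(dec, 1703)
  expect_equal(fr2$prop_censored, 1)
  expect_true(is.na(fr2$median_year))
  toy <- mu_matrix(rbind(c(5, 3, 4, 6), c(5, 4, 6, 2), c(5, 1, 2, 3)) * 1e4)
  colnames(toy) <- as.character(1700:1703)
  fr3 <- first_return_year(toy, 1700)
  expect_equal(fr3$years, c(1703, 1702, NA))
})

test_that("summary quantiles are monotone in the nominal level", {
  ft <- cached_tiny_fit()
  s <- population_summary(ft)
  expect_true(all(s$q2.5 <= s$mean & s$mean <= s$q97.5))
})

test_that("posterior predictive replication reproduces degenerate draws", {
  # a synthetic one-draw 'fit' with near-zero noise: replications must
  # coincide with the latent path at the censuses
  scen <- tiny_scenario()
  scen$truth$sigma_c <- 1e-6
  scen$truth$psi_mu <- 5e4
  ds <- simulate_dataset(scen, 13)
  lat <- ds$truth$latent
  cfg <- scen$config
  T_e <- length(cfg$event_years); p <- cfg$n_units_included
  nrep <- 5
  fake <- structure(list(
    params = do.call(rbind, replicate(2, data.frame(
      chain = 1, iter = 1, sigma_c = 1e-6, psi_mu = 5e4,
      pi = scen$truth$pi, phi_d = scen$truth$phi_d, psi_bd = 1e5,
      sigma_b_nu = 0.01, sigma_d_nu = 0.01, sigma_b_eta = 0.001,
      sigma_d_eta = 0.001, r_b = 0.1, r_d = 0.1, m_b = 1715, m_d = 1715,
      lambda_end = scen$truth$lambda_end, a1 = scen$truth$a[1],
      a2 = scen$truth$a[2], a3 = scen$truth$a[3]), simplify = FALSE)),
    mu = rbind(unname(lat$mu), unname(lat$mu)),
    lambda_b = rbind(lat$lambda_b, lat$lambda_b),
    lambda_d = rbind(lat$lambda_d, lat$lambda_d),
    beta = rbind(lat$beta, lat$beta), delta = rbind(lat$delta, lat$delta),
    nu_b = array(rep(lat$nu_b, each = 2), c(2, T_e, p)),
    nu_d = array(rep(lat$nu_d, each = 2), c(2, T_e, p)),
    eta_b = rbind(lat$eta_b, lat$eta_b), eta_d = rbind(lat$eta_d, lat$eta_d),
    data = ds$data, config = cfg
  ), class = "pop_fit")
  colnames(fake$mu) <- cfg$years
  ppc <- posterior_predictive(fake, n_rep = nrep, seed = 4)
  expect_equal(dim(ppc$mu_rep), c(nrep, length(cfg$years)))
  expect_equal(ppc$n_failed, 0L)
  # with psi_bd and psi_mu huge and sigma_c ~ 0, the replicated censuses
  # stay within a small fraction of the latent path
  idx <- match(cfg$census_years, cfg$years)
  rel <- abs(t(ppc$census_rep) - lat$mu[idx]) / lat$mu[idx]
  expect_true(all(rel < 0.05))
})
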