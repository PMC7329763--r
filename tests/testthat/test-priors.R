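test_that("census-noise prior interval matches the published rounding", {
  sp <- prior_spec("gamma-shape-rate", 1, 1e-4)
  q <- prior_quantile(sp, c(0.025, 0.975))
  expect_equal(round(q[1]), 253)
  expect_equal(round(q[2]), 36889)
})

test_that("initial-population prior moments and interval reproduce", {
  sp <- prior_spec("gamma-shape-rate", 215, 5e-4)
  mo <- prior_moments(sp)
  expect_equal(mo$mean, 430000)
  expect_equal(round(mo$sd), 29326)
  q <- prior_quantile(sp, c(0.025, 0.975))
  expect_equal(round(q[1]), 374440)
  expect_equal(round(q[2]), 489348)
})

test_that("mean/precision beta conversion and the survival-ratio prior", {
  ab <- beta_from_mean_precision(0.775, 200)
  expect_equal(unname(ab), c(155, 45))
  expect_equal(unname(beta_from_mean_precision(0.5, 2)), c(1, 1))
  # mean is recovered
  expect_equal(ab[["alpha"]] / sum(ab), 0.775)
  sp <- prior_spec("beta-mean-precision", 0.775, 200)
  q99 <- prior_quantile(sp, c(0.005, 0.995))
  # published values agree to one unit in the last printed digit
  expect_true(all(abs(q99 - c(0.695, 0.845)) <= 1e-3))
  # independent oracle: root-find the incomplete-beta inverse
  inv <- vapply(c(0.005, 0.995), function(pr) {
    stats::uniroot(function(x) stats::pbeta(x, 155, 45) - pr,
                   c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  }, numeric(1))
  expect_equal(q99, inv, tolerance = 1e-9)
  expect_error(beta_from_mean_precision(1.2, 10), "mean")
})

test_that("Dirichlet aggregation gives the published share intervals", {
  expect_equal(dirichlet_marginal(c(10, 5, 5), 1)$parameters, c(10, 10))
  expect_equal(dirichlet_marginal(c(10, 5, 5), 1:2)$parameters, c(15, 5))
  q1 <- prior_quantile(dirichlet_marginal(c(10, 5, 5), 1), c(0.025, 0.975))
  expect_equal(round(q1, 2), c(0.29, 0.71))
  q12 <- prior_quantile(dirichlet_marginal(c(10, 5, 5), 1:2), c(0.025, 0.975))
  expect_equal(round(q12, 2), c(0.54, 0.91))
  expect_error(dirichlet_marginal(c(10, 5, 5), 1:3), "proper subset")
})

test_that("aggregated marginals match Monte-Carlo Dirichlet draws", {
  set.seed(42)
  draws <- rdirichlet(2e5, c(10, 5, 5))
  mo <- prior_moments(dirichlet_marginal(c(10, 5, 5), 1))
  se <- mo$sd / sqrt(nrow(draws))
  expect_lt(abs(mean(draws[, 1]) - mo$mean), 4 * se)
  mo12 <- prior_moments(dirichlet_marginal(c(10, 5, 5), 1:2))
  expect_lt(abs(mean(draws[, 1] + draws[, 2]) - mo12$mean), 4 * se)
  expect_lt(abs(stats::sd(draws[, 1]) - mo$sd), 0.01)
})

test_that("terminal coverage prior has the published lower bound and mean", {
  sp <- prior_spec("beta-ab", 10 * 177 / 197, 10 * (1 - 177 / 197))
  expect_equal(round(prior_quantile(sp, 0.025), 2), 0.66)
  expect_equal(round(prior_moments(sp)$mean, 3), 0.898)
})

test_that("quantile then CDF is the identity across families", {
  specs <- list(prior_spec("gamma-shape-rate", 2, 4),
                prior_spec("normal-sd", 2, 0.25),
                prior_spec("beta-ab", 5, 5),
                prior_spec("beta-mean-precision", 0.775, 200),
                prior_spec("lognormal", 2, 0.25))
  probs <- seq(0.01, 0.99, by = 0.07)
  for (sp in specs) {
    expect_equal(prior_cdf(sp, prior_quantile(sp, probs)), probs,
                 tolerance = 1e-10)
  }
  # symmetric beta median
  expect_equal(prior_quantile(prior_spec("beta-ab", 5, 5), 0.5), 0.5)
})

test_that("lognormal moments and invalid specs behave", {
  mo <- prior_moments(prior_spec("lognormal", 2, 0.25))
  expect_equal(mo$mean, exp(2 + 0.25^2 / 2))
  expect_error(prior_spec("gamma-shape-rate", -1, 2), "invalid")
  expect_error(prior_quantile(prior_spec("gamma-shape-rate", 2, 4), 1.2),
               "strictly")
})

test_that("the prior table covers every model prior with finite summaries", {
  tab <- prior_table(model_config())
  expect_true(all(c("psi_mu", "sigma_c", "pi", "phi_d", "lambda_end",
                    "a1", "a1_plus_a2", "mu_init") %in% tab$quantity))
  expect_true(all(is.finite(tab$mean) & is.finite(tab$q97.5)))
  expect_true(all(tab$q2.5 < tab$q97.5))
})
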