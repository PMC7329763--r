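test_that("simulation is bit-identical for a fixed scenario and seed", {
  scen <- tiny_scenario()
  a <- simulate_dataset(scen, 123)
  b <- simulate_dataset(scen, 123)
  expect_identical(a$data$b, b$data$b)
  expect_identical(a$data$C, b$data$C)
  expect_identical(a$truth$latent$mu, b$truth$latent$mu)
  c <- simulate_dataset(scen, 124)
  expect_false(identical(a$data$b, c$data$b))
})

test_that("the noiseless limit pins censuses and the accounting path", {
  scen <- noiseless_scenario()
  ds <- simulate_dataset(scen, 2)
  mu <- ds$truth$latent$mu
  idx <- match(scen$config$census_years, scen$config$years)
  # sigma_c = 30 on populations around 430,000
  expect_true(all(abs(ds$data$C - mu[idx]) < 5 * 30))
  # transitions are tight: the path tracks its own accounting increments
  inc <- ds$truth$latent$beta - ds$truth$latent$delta
  expect_true(all(abs(diff(mu) - inc) / mu[-1] < 0.005))
  # full availability under the all-onsets-at-start schedule
  expect_true(all(ds$data$avail_b) && all(ds$data$avail_d))
})

test_that("simulated counts have mean exp(nu) (gamma-mean oracle)", {
  set.seed(31)
  nu <- 3.7; psi <- 0.33; n <- 1e4
  draws <- rgamma(n, shape = psi * exp(nu), rate = psi)
  se <- sqrt(exp(nu) / psi / n)   # var = shape / rate^2 = exp(nu) / psi
  expect_lt(abs(mean(draws) - exp(nu)), 3 * se)
})

test_that("availability schedules follow the requested curve", {
  span <- 1701:1760
  # deterministic onsets at the span start give full availability
  full <- availability_schedule("onset-deterministic",
                                list(rate = 100, midpoint = 1600),
                                span, 6)
  expect_true(all(full))
  # a steep logistic becomes a step at the midpoint
  step <- availability_schedule("onset-deterministic",
                                list(rate = 1000, midpoint = 1730),
                                span, 6)
  expect_true(all(!step[span < 1730, ]))
  expect_true(all(step[span > 1731, ]))
  # random mode: realized fraction within binomial bounds of the curve
  set.seed(5)
  p_units <- 40
  mask <- availability_schedule("logistic-random",
                                list(rate = 0.15, midpoint = 1725),
                                span, p_units)
  curve <- stats::plogis(0.15 * (span - 1725))
  frac <- rowMeans(mask)
  bound <- 4 * sqrt(curve * (1 - curve) / p_units) + 1e-9
  expect_true(all(abs(frac - curve) <= bound))
  # gap years blank all units
  gap <- availability_schedule("onset-deterministic",
                               list(rate = 100, midpoint = 1600,
                                    gap_years = 1713:1721),
                               span, 6)
  expect_true(all(!gap[span %in% 1713:1721, ]))
  expect_true(all(gap[span == 1722, ]))
})

test_that("the joint density is finite at the simulator's own truth", {
  scen <- tiny_scenario()
  for (seed in c(3, 8, 21)) {
    ds <- simulate_dataset(scen, seed)
    lat <- ds$truth$latent
    latent <- list(mu = lat$mu, nu_b = lat$nu_b, nu_d = lat$nu_d,
                   eta_b = lat$eta_b, eta_d = lat$eta_d,
                   b_hat = lat$counts_b, d_hat = lat$counts_d)
    jl <- joint_logpdf(ds$truth$params, latent, ds$data, scen$config)
    expect_true(is.finite(jl))
  }
})

test_that("census residuals are normal at the stated noise level", {
  # many small replications pooled to ~10^4 residuals; a census every
  # year keeps the number of replications manageable
  scen <- tiny_scenario()
  scen$config$census_years <- scen$config$event_years
  sd_c <- scen$truth$sigma_c
  resid <- numeric(0)
  seed <- 400
  while (length(resid) < 1e4) {
    seed <- seed + 1
    ds <- try(simulate_dataset(scen, seed), silent = TRUE)
    if (inherits(ds, "try-error")) next
    idx <- match(scen$config$census_years, scen$config$years)
    resid <- c(resid, ds$data$C - ds$truth$latent$mu[idx])
  }
  ks <- suppressWarnings(stats::ks.test(resid / sd_c, "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("an infeasible scenario reports the offending year", {
  scen <- tiny_scenario()
  # drive deaths far above the population scale
  scen$mu_init <- 500
  expect_error(simulate_dataset(scen, 1), "non-positive at year")
})
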