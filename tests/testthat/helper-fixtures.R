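# Shared fixtures, all generated in code.

# Small fast scenario for fits inside unit tests: 5 units, 30 years,
# crisis in the middle, censuses in the second half.
tiny_scenario <- function() desk_scenario(n_units = 5L, n_years = 30L)

# Raw per-parish event table: 5 parishes grouped into 3 units over
# 10 years, with deterministic counts so grouped sums can be recomputed
# by hand in the tests.
raw_event_fixture <- function() {
  parishes <- paste0("par", 1:5)
  years <- 1701:1710
  rows <- expand.grid(unit_id = parishes, year = years,
                      event_type = c("baptism", "burial"),
                      stringsAsFactors = FALSE)
  # deterministic counts: parish index * 10 + year offset (+3 burial)
  pidx <- as.integer(sub("par", "", rows$unit_id))
  rows$count <- pidx * 10 + (rows$year - 1700) +
    ifelse(rows$event_type == "burial", 3L, 0L)
  # knock out some parish-years to exercise availability handling
  drop <- with(rows, (unit_id == "par2" & year < 1704) |
                 (unit_id == "par5" & year %in% c(1706, 1707) &
                    event_type == "burial"))
  rows[!drop, ]
}

unit_map_fixture <- function() {
  data.frame(raw_id = paste0("par", 1:5),
             unit_id = c("A", "A", "B", "B", "C"),
             stringsAsFactors = FALSE)
}

# Dirichlet sampler used as an independent oracle.
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              n, length(alpha), byrow = TRUE)
  g / rowSums(g)
}

# Random admissible model parameters for property tests.
random_params <- function(config) {
  a_raw <- stats::rgamma(3, shape = c(10, 5, 5))
  list(
    sigma_c = stats::runif(1, 100, 5000),
    psi_mu = stats::runif(1, 0.1, 2),
    pi = stats::runif(1, 0.6, 0.9),
    phi_d = stats::runif(1, 2, 9),
    psi_bd = stats::runif(1, 0.1, 1),
    sigma_b_nu = stats::runif(1, 0.02, 0.4),
    sigma_d_nu = stats::runif(1, 0.02, 0.4),
    sigma_b_eta = stats::runif(1, 0.002, 0.1),
    sigma_d_eta = stats::runif(1, 0.002, 0.1),
    r_b = stats::runif(1, 0.02, 0.3),
    r_d = stats::runif(1, 0.02, 0.3),
    m_b = config$t_start + config$midpoint_span * stats::runif(1, 0.2, 0.8),
    m_d = config$t_start + config$midpoint_span * stats::runif(1, 0.2, 0.8),
    a = a_raw / sum(a_raw),
    lambda_end = stats::runif(1, 0.6, 0.98)
  )
}

# Random latent state consistent with a dataset's dimensions.
random_latent <- function(data, config) {
  T_all <- length(config$years)
  T_e <- length(config$event_years)
  p <- data$n_units_included
  list(
    mu = stats::runif(T_all, 3e5, 6e5),
    nu_b = matrix(stats::rnorm(T_e * p, 3.8, 0.4), T_e, p),
    nu_d = matrix(stats::rnorm(T_e * p, 3.2, 0.4), T_e, p),
    eta_b = cumsum(stats::rnorm(T_e, 0, 0.005)),
    eta_d = cumsum(stats::rnorm(T_e, 0, 0.005)),
    b_hat = matrix(stats::rgamma(T_e * p, 40, 1), T_e, p),
    d_hat = matrix(stats::rgamma(T_e * p, 25, 1), T_e, p)
  )
}

# One small cached fit shared by the tests that only need *a* posterior
# sample, so the suite pays for it once.
cached_tiny_fit <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      scen <- tiny_scenario()
      ds <- simulate_dataset(scen, 7)
      val <<- suppressWarnings(
        fit(ds$data, scen$config,
            fit_config(chains = 2, iter = 220, warmup = 100, seed = 3,
                       target_accept = 0.7)))
      attr(val, "dataset") <<- ds
    }
    val
  }
})
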