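#' Sampler configuration
#'
#' Desk-scale default: 4 chains of 1,500 iterations with 500 discarded as
#' warm-up. The full-scale historical preset (16 chains of 12,500 with
#' 2,500 warm-up) is available as `fit_config(preset = "full")`.
#'
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param iter Iterations per chain, including warm-up.
#' @param warmup Warm-up iterations per chain.
#' @param seed Integer RNG seed.
#' @param target_accept NUTS dual-averaging acceptance target.
#' @param max_treedepth Maximum trajectory doublings per iteration.
#' @param divergence_warn Warn when the post-warm-up divergence rate
#'   exceeds this fraction (default 0.01).
#' @param init_jitter SD of the jitter added to the skeleton
#'   initialisation on the unconstrained scale.
#' @param store_latent Keep per-draw latent log-intensity walks (needed
#'   for posterior predictive replication).
#' @param preset `"desk"` (default) or `"full"`.
#' @export
fit_config <- function(chains = 4L, iter = 1500L, warmup = 500L, seed = 1L,
                       target_accept = 0.8, max_treedepth = 8L,
                       divergence_warn = 0.01, init_jitter = 0.02,
                       store_latent = TRUE,
                       preset = c("desk", "full")) {
  preset <- match.arg(preset)
  if (preset == "full") {
    chains <- 16L; iter <- 12500L; warmup <- 2500L
  }
  stopifnot(warmup < iter, chains >= 1L)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 target_accept = target_accept,
                 max_treedepth = as.integer(max_treedepth),
                 divergence_warn = divergence_warn,
                 init_jitter = init_jitter,
                 store_latent = isTRUE(store_latent)),
            class = "pop_fit_config")
}

#' Fit the population model by NUTS
#'
#' Builds the compiled joint posterior for the data, initialises every
#' chain on the cumulative-sum accounting skeleton with a small jitter,
#' runs the No-U-Turn sampler, and extracts natural-scale posterior draws
#' of all parameters and latent series.
#'
#' @param data An `observed_data` object.
#' @param config A [model_config()] matching the data.
#' @param fit_cfg A [fit_config()].
#' @param fixed Named list of natural-scale parameter values to hold
#'   fixed (e.g. `list(sigma_c = 30, lambda_end = 1)`), for degenerate or
#'   partially known configurations.
#' @return An object of class `pop_fit` with elements
#'   `params` (data frame of scalar draws, one row per saved draw, with
#'   `chain` and `iter` columns), `mu`, `beta`, `delta`, `lambda_b`,
#'   `lambda_d` (draw x time matrices), `phi_mu`, optional `nu_b`,
#'   `nu_d`, `eta_b`, `eta_d` latent arrays, `sampler` diagnostics and
#'   the configurations used.
#' @export
fit <- function(data, config, fit_cfg = fit_config(), fixed = list()) {
  stopifnot(inherits(fit_cfg, "pop_fit_config"))
  obj <- .make_objective(data, config, fixed = fixed)
  init0 <- obj$par
  if (!is.finite(obj$fn(init0))) {
    stop("non-finite joint density at the skeleton initialisation")
  }

  use_cpp <- !isTRUE(attr(obj, "has_map"))
  ptr <- if (use_cpp) pop_model_build(attr(obj, "tmb_data"))
  mass0 <- .initial_mass(obj, ptr)
  chain_out <- vector("list", fit_cfg$chains)
  for (ch in seq_len(fit_cfg$chains)) {
    set.seed((fit_cfg$seed * 1009L + ch) %% 2147483587L)
    jit <- stats::rnorm(length(init0), 0, fit_cfg$init_jitter) / sqrt(mass0)
    init <- init0 + jit
    if (!is.finite(obj$fn(init))) init <- init0
    chain_out[[ch]] <- if (use_cpp) {
      pop_nuts(ptr, init, fit_cfg$iter, fit_cfg$warmup,
               fit_cfg$target_accept, fit_cfg$max_treedepth, mass0,
               .adapt_windows(fit_cfg$warmup))
    } else {
      nuts_chain(obj$fn, obj$gr, init,
                 iter = fit_cfg$iter,
                 warmup = fit_cfg$warmup,
                 target_accept = fit_cfg$target_accept,
                 max_treedepth = fit_cfg$max_treedepth,
                 mass_init = mass0)
    }
  }

  n_keep <- fit_cfg$iter - fit_cfg$warmup
  post_stats <- do.call(rbind, lapply(seq_along(chain_out), function(ch) {
    st <- chain_out[[ch]]$stats[-seq_len(fit_cfg$warmup), , drop = FALSE]
    st$chain <- ch
    st
  }))
  div_rate <- mean(post_stats$divergent)
  if (div_rate > fit_cfg$divergence_warn) {
    warning(sprintf("post-warm-up divergence rate %.1f%% exceeds %.1f%%",
                    100 * div_rate, 100 * fit_cfg$divergence_warn))
  }

  T_all <- length(config$years)
  T_e <- length(config$event_years)
  p <- config$n_units_included
  n_draws <- n_keep * fit_cfg$chains

  params <- matrix(NA_real_, n_draws, 19L)
  colnames(params) <- c("chain", "iter", "sigma_c", "psi_mu", "pi",
                        "phi_d", "psi_bd", "sigma_b_nu", "sigma_d_nu",
                        "sigma_b_eta", "sigma_d_eta", "r_b", "r_d",
                        "m_b", "m_d", "lambda_end", "a1", "a2", "a3")
  mu <- matrix(NA_real_, n_draws, T_all, dimnames = list(NULL, config$years))
  beta <- delta <- lambda_b <- lambda_d <-
    matrix(NA_real_, n_draws, T_e, dimnames = list(NULL, config$event_years))
  phi_mu <- rep(NA_real_, n_draws)
  if (fit_cfg$store_latent) {
    nu_b <- nu_d <- array(NA_real_, c(n_draws, T_e, p))
    eta_b <- eta_d <- matrix(NA_real_, n_draws, T_e)
  }

  row <- 0L
  for (ch in seq_len(fit_cfg$chains)) {
    draws <- chain_out[[ch]]$draws
    for (k in seq_len(n_keep)) {
      row <- row + 1L
      rep_k <- obj$report(draws[k, ])
      params[row, ] <- c(ch, k, rep_k$sigma_c, rep_k$psi_mu, rep_k$pi_,
                         rep_k$phi_d, rep_k$psi_bd, rep_k$sigma_b_nu,
                         rep_k$sigma_d_nu, rep_k$sigma_b_eta,
                         rep_k$sigma_d_eta, rep_k$r_b, rep_k$r_d,
                         rep_k$m_b, rep_k$m_d, rep_k$lam_end, rep_k$a)
      mu[row, ] <- rep_k$mu
      beta[row, ] <- rep_k$beta
      delta[row, ] <- rep_k$delta
      lambda_b[row, ] <- rep_k$lam_b
      lambda_d[row, ] <- rep_k$lam_d
      phi_mu[row] <- rep_k$phi_mu
      if (fit_cfg$store_latent) {
        nu_b[row, , ] <- rep_k$nu_b
        nu_d[row, , ] <- rep_k$nu_d
        eta_b[row, ] <- rep_k$eta_b
        eta_d[row, ] <- rep_k$eta_d
      }
    }
  }

  out <- list(params = as.data.frame(params),
              mu = mu, beta = beta, delta = delta,
              lambda_b = lambda_b, lambda_d = lambda_d, phi_mu = phi_mu,
              sampler = list(stats = post_stats,
                             divergence_rate = div_rate,
                             eps = vapply(chain_out, `[[`, 0, "eps")),
              data = data, config = config, fit_cfg = fit_cfg,
              fixed = fixed)
  if (fit_cfg$store_latent) {
    out$nu_b <- nu_b; out$nu_d <- nu_d
    out$eta_b <- eta_b; out$eta_d <- eta_d
  }
  class(out) <- "pop_fit"
  out
}

#' @export
print.pop_fit <- function(x, ...) {
  cat("pop_fit:", nrow(x$params), "draws,",
      max(x$params$chain), "chains;",
      sprintf("divergence rate %.2f%%\n", 100 * x$sampler$divergence_rate))
  invisible(x)
}

# Initial mass diagonal from the finite-difference diagonal Hessian of
# the negative log posterior at the initialisation point. Coordinate
# scales in this model span several orders of magnitude (log-population
# increments vs. latent intensities vs. unconstrained scalars); starting
# the metric near the local curvature lets warm-up begin with a usable
# step size instead of the smallest scale. Clamped to keep the metric
# positive and bounded; refined by the warm-up windows afterwards.
.initial_mass <- function(obj, ptr = NULL) {
  x0 <- obj$par
  gr <- if (is.null(ptr)) function(x) obj$gr(x) else
    function(x) pop_eval(ptr, x)$gradient
  g0 <- as.numeric(gr(x0))
  h <- numeric(length(x0))
  delta <- 1e-4
  for (i in seq_along(x0)) {
    x1 <- x0
    x1[i] <- x1[i] + delta
    h[i] <- (as.numeric(gr(x1))[i] - g0[i]) / delta
  }
  pmin(pmax(h, 0.25), 1e6)
}

# ---- convergence diagnostics -------------------------------------------

# draws: iterations x chains matrix -> split chains in halves
.split_chains <- function(draws) {
  n <- nrow(draws)
  h <- n %/% 2L
  cbind(draws[seq_len(h), , drop = FALSE],
        draws[(n - h + 1L):n, , drop = FALSE])
}

.rank_normalize <- function(draws) {
  r <- rank(draws, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(draws) + 1 / 4))
  matrix(z, nrow(draws), ncol(draws))
}

# Classic potential-scale-reduction on an iterations x chains matrix.
.rhat_basic <- function(draws) {
  n <- nrow(draws); m <- ncol(draws)
  if (n < 3L || m < 2L) return(NA_real_)
  means <- colMeans(draws)
  vars <- apply(draws, 2, stats::var)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Split R-hat (rank-normalised)
#'
#' @param draws Iterations x chains matrix of draws of one quantity.
#' @return Scalar R-hat; `NA` for a single chain or constant draws.
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  .rhat_basic(.rank_normalize(.split_chains(draws)))
}

# Combined autocorrelation ESS (Geyer initial monotone sequence) on an
# iterations x chains matrix.
.ess_acf <- function(draws) {
  n <- nrow(draws); m <- ncol(draws)
  if (n < 3L) return(NA_real_)
  vars <- apply(draws, 2, stats::var)
  W <- mean(vars)
  if (W == 0 || !is.finite(W)) return(NA_real_)
  means <- colMeans(draws)
  B_n <- if (m > 1L) stats::var(means) else 0
  var_plus <- (n - 1) / n * W + B_n
  max_lag <- n - 2L
  acov <- vapply(seq_len(m), function(c) {
    a <- stats::acf(draws[, c], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(max_lag + 1L))
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus
  rho[1] <- 1
  # Geyer initial monotone sequence on pair sums P_k = rho_2k + rho_2k+1
  P <- numeric(0)
  prev <- Inf
  k <- 1L
  while (k + 1L <= length(rho)) {
    pk <- rho[k] + rho[k + 1L]
    if (pk < 0) break
    pk <- min(pk, prev)
    prev <- pk
    P <- c(P, pk)
    k <- k + 2L
  }
  tau <- max(2 * sum(P) - rho[1], 1 / log10(n * m + 10))
  n * m / tau
}

#' Effective sample size (rank-normalised, split chains)
#'
#' @inheritParams split_rhat
#' @export
ess_bulk <- function(draws) {
  draws <- as.matrix(draws)
  .ess_acf(.rank_normalize(.split_chains(draws)))
}

#' Effective sample size of the raw draws (for MCSE)
#' @inheritParams split_rhat
#' @export
ess_mean <- function(draws) {
  .ess_acf(.split_chains(as.matrix(draws)))
}

#' Posterior summary and convergence diagnostics
#'
#' Per quantity: posterior mean, Monte Carlo standard error of the mean,
#' SD, the 2.5/25/50/75/97.5% quantiles, effective sample size
#' (rank-normalised bulk ESS) and split R-hat. With a single chain R-hat
#' is reported as `NA`.
#'
#' @param fit A `pop_fit`, or a named list of iterations x chains
#'   matrices.
#' @param quantities For a `pop_fit`: which scalar parameters to report
#'   (default all), plus `phi_mu` when a crisis year is configured.
#' @return A data frame, one row per quantity.
#' @export
diagnostics <- function(fit, quantities = NULL) {
  if (inherits(fit, "pop_fit")) {
    chains <- fit$params$chain
    n_chain <- max(chains)
    scalars <- setdiff(colnames(fit$params), c("chain", "iter"))
    if (!is.null(quantities)) scalars <- intersect(scalars, quantities)
    mats <- lapply(scalars, function(nm) {
      vapply(seq_len(n_chain),
             function(ch) fit$params[[nm]][chains == ch],
             numeric(sum(chains == 1L)))
    })
    names(mats) <- scalars
    if ((is.null(quantities) || "phi_mu" %in% quantities) &&
        !all(is.na(fit$phi_mu))) {
      mats$phi_mu <- vapply(seq_len(n_chain),
                            function(ch) fit$phi_mu[chains == ch],
                            numeric(sum(chains == 1L)))
    }
  } else {
    mats <- lapply(fit, as.matrix)
  }
  rows <- lapply(names(mats), function(nm) {
    m <- mats[[nm]]
    x <- as.numeric(m)
    qs <- stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
    ess_m <- ess_mean(m)
    data.frame(quantity = nm, mean = mean(x),
               mcse = stats::sd(x) / sqrt(ess_m),
               sd = stats::sd(x),
               q2.5 = qs[1], q25 = qs[2], q50 = qs[3], q75 = qs[4],
               q97.5 = qs[5],
               ess = ess_bulk(m),
               rhat = if (ncol(m) >= 2L) split_rhat(m) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reconstruct per-unit imputed counts from a fit
#'
#' The sampler integrates the per-unit imputed counts into their per-year
#' totals (exact, by gamma additivity). Conditionally on the total and
#' the latent intensities, the per-unit counts are the total multiplied
#' by a Dirichlet split with the per-unit gamma shapes; this function
#' draws them for a subset of posterior draws.
#'
#' @param fit A `pop_fit` with stored latent intensities.
#' @param draw_ids Integer indices of the draws to reconstruct (default
#'   all).
#' @param seed Integer seed for the conditional draws.
#' @return List with arrays `b_hat` and `d_hat` (draw x year x unit;
#'   `NA` where the unit-year was observed).
#' @export
impute_unit_counts <- function(fit, draw_ids = NULL, seed = 1L) {
  stopifnot(inherits(fit, "pop_fit"))
  if (is.null(fit$nu_b)) stop("fit was run with store_latent = FALSE")
  set.seed(as.integer(seed))
  if (is.null(draw_ids)) draw_ids <- seq_len(nrow(fit$params))
  cfg <- fit$config
  data <- fit$data
  T_e <- length(cfg$event_years)
  p <- cfg$n_units_included
  crisis_e <- if (is.null(cfg$crisis_year)) 0L else
    match(cfg$crisis_year, cfg$event_years)
  out_b <- array(NA_real_, c(length(draw_ids), T_e, p))
  out_d <- array(NA_real_, c(length(draw_ids), T_e, p))
  # observed counts on the scale the likelihood saw (zeros offset)
  b_off <- data$b; b_off[data$avail_b & b_off <= 0] <- cfg$zero_offset
  d_off <- data$d; d_off[data$avail_d & d_off <= 0] <- cfg$zero_offset
  for (j in seq_along(draw_ids)) {
    k <- draw_ids[j]
    psi <- fit$params$psi_bd[k]
    for (t in seq_len(T_e)) {
      miss_b <- !data$avail_b[t, ]
      if (any(miss_b)) {
        shapes <- psi * exp(fit$nu_b[k, t, miss_b])
        tot <- fit$beta[k, t] * fit$lambda_b[k, t] -
          sum(b_off[t, !miss_b], na.rm = TRUE)
        g <- stats::rgamma(sum(miss_b), shape = shapes, rate = 1)
        out_b[j, t, miss_b] <- tot * g / sum(g)
      }
      miss_d <- !data$avail_d[t, ]
      if (any(miss_d)) {
        cf <- if (t == crisis_e) fit$params$phi_d[k] else 1
        shapes <- psi * cf * exp(fit$nu_d[k, t, miss_d])
        tot <- fit$delta[k, t] * fit$lambda_d[k, t] -
          sum(d_off[t, !miss_d], na.rm = TRUE)
        g <- stats::rgamma(sum(miss_d), shape = shapes, rate = 1)
        out_d[j, t, miss_d] <- tot * g / sum(g)
      }
    }
  }
  list(b_hat = out_b, d_hat = out_d)
}
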