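# No-U-Turn sampler (Hoffman & Gelman 2014, slice variant) with
# dual-averaging step-size adaptation and diagonal mass-matrix estimation
# in doubling warm-up windows, over an arbitrary negative-log-density
# `fn` and gradient `gr` (here the TMB-compiled joint posterior).
# Non-finite energies or energy errors beyond `divergence_threshold`
# count as divergences and reject the subtree.

.nuts_divergence_threshold <- 1000

# One leapfrog step. `mass` is the diagonal metric (momentum covariance);
# velocities are p / mass.
.leapfrog <- function(q, p, grad, eps, fn, gr, mass) {
  p <- p - 0.5 * eps * grad
  q <- q + eps * p / mass
  grad_new <- as.numeric(gr(q))
  p <- p - 0.5 * eps * grad_new
  list(q = q, p = p, grad = grad_new, U = as.numeric(fn(q)))
}

.energy <- function(U, p, mass) U + 0.5 * sum(p * p / mass)

# Recursive doubling of the trajectory (Algorithm 6).
.build_tree <- function(state, log_u, dir, depth, eps, H0, fn, gr, mass) {
  if (depth == 0L) {
    st <- .leapfrog(state$q, state$p, state$grad, dir * eps, fn, gr, mass)
    H <- .energy(st$U, st$p, mass)
    if (!is.finite(H)) H <- Inf
    n_valid <- as.integer(log_u <= -H)
    diverged <- (log_u - .nuts_divergence_threshold) > -H
    alpha <- min(1, exp(H0 - H))
    if (!is.finite(alpha)) alpha <- 0
    return(list(minus = st, plus = st, prop = st, n = n_valid,
                stop = diverged, alpha = alpha, n_alpha = 1L,
                diverged = diverged))
  }
  left <- .build_tree(state, log_u, dir, depth - 1L, eps, H0, fn, gr, mass)
  if (left$stop) return(left)
  inner <- if (dir == -1) left$minus else left$plus
  right <- .build_tree(inner, log_u, dir, depth - 1L, eps, H0, fn, gr, mass)
  minus <- if (dir == -1) right$minus else left$minus
  plus <- if (dir == -1) left$plus else right$plus
  n_tot <- left$n + right$n
  prop <- left$prop
  if (n_tot > 0L && stats::runif(1) < right$n / n_tot) prop <- right$prop
  dq <- plus$q - minus$q
  uturn <- sum(dq * (minus$p / mass)) < 0 || sum(dq * (plus$p / mass)) < 0
  list(minus = minus, plus = plus, prop = prop, n = n_tot,
       stop = right$stop || uturn,
       alpha = left$alpha + right$alpha,
       n_alpha = left$n_alpha + right$n_alpha,
       diverged = left$diverged || right$diverged)
}

# Reasonable initial step size (Algorithm 4).
.find_initial_eps <- function(q, fn, gr, mass) {
  eps <- 0.1
  U0 <- as.numeric(fn(q))
  grad0 <- as.numeric(gr(q))
  p0 <- stats::rnorm(length(q)) * sqrt(mass)
  H0 <- .energy(U0, p0, mass)
  st <- .leapfrog(q, p0, grad0, eps, fn, gr, mass)
  H1 <- .energy(st$U, st$p, mass)
  while (!is.finite(H1) && eps > 1e-10) {
    eps <- eps / 2
    st <- .leapfrog(q, p0, grad0, eps, fn, gr, mass)
    H1 <- .energy(st$U, st$p, mass)
  }
  a <- if (H0 - H1 > log(0.5)) 1 else -1
  for (k in 1:50) {
    eps <- eps * 2^a
    st <- .leapfrog(q, p0, grad0, eps, fn, gr, mass)
    H1 <- .energy(st$U, st$p, mass)
    if (!is.finite(H1)) H1 <- Inf
    if (a * (H0 - H1) < a * log(0.5)) break
  }
  max(eps, 1e-10)
}

# Warm-up schedule: step-size-only buffers around doubling covariance
# windows, in the spirit of Stan's windowed adaptation.
.adapt_windows <- function(warmup) {
  if (warmup < 20L) return(integer(0))
  init_buf <- max(5L, floor(0.15 * warmup))
  term_buf <- max(5L, floor(0.1 * warmup))
  ends <- integer(0)
  w <- max(10L, floor((warmup - init_buf - term_buf) / 4))
  pos <- init_buf
  while (pos + w <= warmup - term_buf) {
    pos <- pos + w
    # last window absorbs the remainder
    if (pos + 2L * w > warmup - term_buf) pos <- warmup - term_buf
    ends <- c(ends, pos)
    w <- 2L * w
  }
  ends
}

#' No-U-Turn sampling of one chain
#'
#' @param fn Negative log density (potential energy).
#' @param gr Its gradient.
#' @param init Numeric initial position.
#' @param iter Total iterations including warm-up.
#' @param warmup Number of warm-up (adaptation) iterations.
#' @param target_accept Dual-averaging acceptance target (default 0.8).
#' @param max_treedepth Maximum trajectory doublings (default 8).
#' @param mass_init Optional initial diagonal of the mass matrix
#'   (momentum variances, i.e. inverse squared position scales); default
#'   identity. Refined during warm-up.
#' @return List with post-warm-up `draws` (matrix), per-iteration sampler
#'   `stats` (treedepth, divergence, energy, acceptance), the adapted
#'   step size and the mass-matrix diagonal.
#' @keywords internal
nuts_chain <- function(fn, gr, init, iter, warmup,
                       target_accept = 0.8, max_treedepth = 8L,
                       mass_init = NULL) {
  n <- length(init)
  q <- init
  mass <- if (is.null(mass_init)) rep(1, n) else mass_init
  stopifnot(length(mass) == n, all(mass > 0))
  U <- as.numeric(fn(q))
  if (!is.finite(U)) stop("non-finite joint density at the initial state")
  grad <- as.numeric(gr(q))

  eps <- .find_initial_eps(q, fn, gr, mass)
  da_mu <- log(10 * eps)
  da_logbar <- 0; da_h <- 0; da_count <- 0L
  da_gamma <- 0.05; da_t0 <- 10; da_kappa <- 0.75
  windows <- .adapt_windows(warmup)
  win_buf <- list()

  keep <- matrix(NA_real_, max(iter - warmup, 0L), n)
  stats <- data.frame(treedepth = integer(iter), divergent = logical(iter),
                      energy = numeric(iter), accept = numeric(iter))

  for (it in seq_len(iter)) {
    p0 <- stats::rnorm(n) * sqrt(mass)
    H0 <- .energy(U, p0, mass)
    log_u <- log(stats::runif(1)) - H0
    st0 <- list(q = q, p = p0, grad = grad, U = U)
    minus <- st0; plus <- st0
    n_tot <- 1L; depth <- 0L
    alpha_sum <- 0; n_alpha <- 0L; diverged <- FALSE
    while (depth < max_treedepth) {
      dir <- if (stats::runif(1) < 0.5) -1 else 1
      edge <- if (dir == -1) minus else plus
      tree <- .build_tree(edge, log_u, dir, depth, eps, H0, fn, gr, mass)
      if (dir == -1) minus <- tree$minus else plus <- tree$plus
      alpha_sum <- alpha_sum + tree$alpha
      n_alpha <- n_alpha + tree$n_alpha
      diverged <- diverged || tree$diverged
      if (tree$stop) break
      if (tree$n > 0L && stats::runif(1) < tree$n / n_tot) {
        q <- tree$prop$q; U <- tree$prop$U; grad <- tree$prop$grad
      }
      n_tot <- n_tot + tree$n
      depth <- depth + 1L
      dq <- plus$q - minus$q
      if (sum(dq * (minus$p / mass)) < 0 ||
          sum(dq * (plus$p / mass)) < 0) break
    }
    accept_stat <- if (n_alpha > 0L) alpha_sum / n_alpha else 0

    if (it <= warmup) {
      # dual averaging toward the target acceptance
      da_count <- da_count + 1L
      da_h <- (1 - 1 / (da_count + da_t0)) * da_h +
        (target_accept - accept_stat) / (da_count + da_t0)
      log_eps <- da_mu - sqrt(da_count) / da_gamma * da_h
      w_da <- da_count^(-da_kappa)
      da_logbar <- w_da * log_eps + (1 - w_da) * da_logbar
      eps <- exp(log_eps)
      win_buf[[length(win_buf) + 1L]] <- q
      if (it %in% windows) {
        draws_win <- do.call(rbind, win_buf)
        v <- apply(draws_win, 2, stats::var)
        m <- nrow(draws_win)
        v <- v * m / (m + 5) + 1e-3 * 5 / (m + 5)
        mass <- 1 / v
        win_buf <- list()
        eps <- .find_initial_eps(q, fn, gr, mass)
        da_mu <- log(10 * eps)
        da_logbar <- 0; da_h <- 0; da_count <- 0L
      }
      if (it == warmup) eps <- exp(da_logbar)
    } else {
      keep[it - warmup, ] <- q
    }
    stats$treedepth[it] <- depth
    stats$divergent[it] <- diverged
    stats$energy[it] <- H0
    stats$accept[it] <- accept_stat
  }
  list(draws = keep, stats = stats, eps = eps, mass = mass)
}
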