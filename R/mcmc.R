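# No-U-Turn sampler with dual-averaging step-size adaptation.
#
# The ideology models fitted here are two- and three-parameter posteriors with
# cheap analytic gradients, sampled on an unconstrained scale (scale parameters
# are log-transformed by the caller, with the Jacobian folded into the target).
# The sampler is the classic recursive formulation: a slice variable drawn at
# each iteration, trajectory doubling until the no-U-turn criterion fires, and
# multinomial-uniform selection among valid states. Identity mass matrix;
# step size adapted during warm-up toward a target acceptance statistic.

nuts_max_treedepth <- 10L
nuts_delta_max <- 1000

leapfrog <- function(theta, r, eps, grad_fn) {
  r <- r + 0.5 * eps * grad_fn(theta)
  theta <- theta + eps * r
  r <- r + 0.5 * eps * grad_fn(theta)
  list(theta = theta, r = r)
}

joint_logp <- function(theta, r, logp_fn) logp_fn(theta) - 0.5 * sum(r * r)

find_reasonable_epsilon <- function(theta, logp_fn, grad_fn) {
  eps <- 1
  r <- rnorm(length(theta))
  j0 <- joint_logp(theta, r, logp_fn)
  prop <- leapfrog(theta, r, eps, grad_fn)
  j1 <- joint_logp(prop$theta, prop$r, logp_fn)
  if (!is.finite(j1)) {
    while (!is.finite(j1) && eps > 1e-10) {
      eps <- eps / 2
      prop <- leapfrog(theta, r, eps, grad_fn)
      j1 <- joint_logp(prop$theta, prop$r, logp_fn)
    }
  }
  a <- if (j1 - j0 > log(0.5)) 1 else -1
  while (a * (j1 - j0) > -a * log(2)) {
    eps <- eps * 2^a
    if (eps > 1e7 || eps < 1e-10) break
    prop <- leapfrog(theta, r, eps, grad_fn)
    j1 <- joint_logp(prop$theta, prop$r, logp_fn)
    if (!is.finite(j1)) j1 <- -Inf
  }
  eps
}

build_tree <- function(theta, r, log_u, v, j, eps, joint0, logp_fn, grad_fn) {
  if (j == 0L) {
    prop <- leapfrog(theta, r, v * eps, grad_fn)
    jp <- joint_logp(prop$theta, prop$r, logp_fn)
    if (!is.finite(jp)) jp <- -Inf
    n_prime <- as.integer(log_u <= jp)
    s_prime <- as.integer(log_u < jp + nuts_delta_max)
    list(theta_minus = prop$theta, r_minus = prop$r,
         theta_plus = prop$theta, r_plus = prop$r,
         theta_prime = prop$theta, n_prime = n_prime, s_prime = s_prime,
         alpha = min(1, exp(jp - joint0)), n_alpha = 1L,
         divergent = s_prime == 0L)
  } else {
    t1 <- build_tree(theta, r, log_u, v, j - 1L, eps, joint0, logp_fn, grad_fn)
    theta_minus <- t1$theta_minus; r_minus <- t1$r_minus
    theta_plus <- t1$theta_plus; r_plus <- t1$r_plus
    theta_prime <- t1$theta_prime
    n_prime <- t1$n_prime; s_prime <- t1$s_prime
    alpha <- t1$alpha * t1$n_alpha; n_alpha <- t1$n_alpha
    divergent <- t1$divergent
    if (s_prime == 1L) {
      if (v == -1) {
        t2 <- build_tree(theta_minus, r_minus, log_u, v, j - 1L, eps, joint0,
                         logp_fn, grad_fn)
        theta_minus <- t2$theta_minus; r_minus <- t2$r_minus
      } else {
        t2 <- build_tree(theta_plus, r_plus, log_u, v, j - 1L, eps, joint0,
                         logp_fn, grad_fn)
        theta_plus <- t2$theta_plus; r_plus <- t2$r_plus
      }
      if (t2$n_prime > 0L &&
          runif(1) < t2$n_prime / max(1L, n_prime + t2$n_prime)) {
        theta_prime <- t2$theta_prime
      }
      alpha <- alpha + t2$alpha * t2$n_alpha
      n_alpha <- n_alpha + t2$n_alpha
      dtheta <- theta_plus - theta_minus
      s_prime <- t2$s_prime *
        as.integer(sum(dtheta * r_minus) >= 0) *
        as.integer(sum(dtheta * r_plus) >= 0)
      n_prime <- n_prime + t2$n_prime
      divergent <- divergent || t2$divergent
    }
    list(theta_minus = theta_minus, r_minus = r_minus,
         theta_plus = theta_plus, r_plus = r_plus,
         theta_prime = theta_prime, n_prime = n_prime, s_prime = s_prime,
         alpha = alpha / max(1L, n_alpha), n_alpha = n_alpha,
         divergent = divergent)
  }
}

nuts_chain <- function(logp_fn, grad_fn, init, n_warmup, n_draws,
                       target_accept = 0.8) {
  d <- length(init)
  theta <- init
  eps <- find_reasonable_epsilon(theta, logp_fn, grad_fn)
  mu <- log(10 * eps)
  eps_bar <- 1
  h_bar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  total <- n_warmup + n_draws
  draws <- matrix(NA_real_, nrow = n_draws, ncol = d)
  divergences <- 0L
  for (m in seq_len(total)) {
    r0 <- rnorm(d)
    joint0 <- joint_logp(theta, r0, logp_fn)
    log_u <- joint0 - rexp(1)
    theta_minus <- theta; theta_plus <- theta
    r_minus <- r0; r_plus <- r0
    j <- 0L; theta_m <- theta; n <- 1L; s <- 1L
    alpha <- 0; n_alpha <- 1L
    while (s == 1L && j < nuts_max_treedepth) {
      v <- sample(c(-1, 1), 1)
      if (v == -1) {
        tr <- build_tree(theta_minus, r_minus, log_u, v, j, eps, joint0,
                         logp_fn, grad_fn)
        theta_minus <- tr$theta_minus; r_minus <- tr$r_minus
      } else {
        tr <- build_tree(theta_plus, r_plus, log_u, v, j, eps, joint0,
                         logp_fn, grad_fn)
        theta_plus <- tr$theta_plus; r_plus <- tr$r_plus
      }
      if (tr$s_prime == 1L && tr$n_prime > 0L &&
          runif(1) < min(1, tr$n_prime / n)) {
        theta_m <- tr$theta_prime
      }
      n <- n + tr$n_prime
      dtheta <- theta_plus - theta_minus
      s <- tr$s_prime *
        as.integer(sum(dtheta * r_minus) >= 0) *
        as.integer(sum(dtheta * r_plus) >= 0)
      alpha <- tr$alpha; n_alpha <- tr$n_alpha
      if (m > n_warmup && tr$divergent) divergences <- divergences + 1L
      j <- j + 1L
    }
    theta <- theta_m
    if (m <= n_warmup) {
      frac <- 1 / (m + t0)
      h_bar <- (1 - frac) * h_bar + frac * (target_accept - alpha)
      log_eps <- mu - sqrt(m) / gamma * h_bar
      eta <- m^(-kappa)
      eps_bar <- exp(eta * log_eps + (1 - eta) * log(eps_bar))
      eps <- exp(log_eps)
    } else {
      eps <- eps_bar
      draws[m - n_warmup, ] <- theta
    }
  }
  list(draws = draws, divergences = divergences, step_size = eps_bar)
}

# Split R-hat (rank-free classic form) computed over chains split in half.
split_rhat <- function(draw_list) {
  halves <- list()
  for (m in draw_list) {
    n <- nrow(m)
    if (n < 4) return(rep(NA_real_, ncol(m)))
    half <- floor(n / 2)
    halves <- c(halves, list(m[seq_len(half), , drop = FALSE]),
                list(m[(n - half + 1):n, , drop = FALSE]))
  }
  vapply(seq_len(ncol(draw_list[[1]])), function(k) {
    x <- vapply(halves, function(h) mean(h[, k]), numeric(1))
    w <- vapply(halves, function(h) var(h[, k]), numeric(1))
    n <- nrow(halves[[1]])
    b <- n * var(x)
    wmean <- mean(w)
    if (wmean <= 0) return(1)
    sqrt(((n - 1) / n * wmean + b / n) / wmean)
  }, numeric(1))
}

# Sample a d-dimensional unconstrained posterior with NUTS across chains.
# Returns a matrix of retained draws (rows) with diagnostics attached.
nuts_sample <- function(logp_fn, grad_fn, init, chains, n_warmup,
                        n_draws_total, seed = NULL, param_names = NULL,
                        target_accept = 0.8) {
  per_chain <- ceiling(n_draws_total / chains)
  run <- function() {
    res <- lapply(seq_len(chains), function(ch) {
      jitter <- if (chains > 1) rnorm(length(init), 0, 0.1) else 0
      nuts_chain(logp_fn, grad_fn, init + jitter, n_warmup, per_chain,
                 target_accept = target_accept)
    })
    res
  }
  res <- with_seed_or_current(seed, run())
  draw_list <- lapply(res, `[[`, "draws")
  draws <- do.call(rbind, draw_list)
  if (nrow(draws) > n_draws_total) {
    draws <- draws[seq_len(n_draws_total), , drop = FALSE]
  }
  if (!is.null(param_names)) colnames(draws) <- param_names
  rhat <- split_rhat(draw_list)
  if (!is.null(param_names)) names(rhat) <- param_names
  attr(draws, "divergences") <- sum(vapply(res, `[[`, integer(1),
                                           "divergences"))
  attr(draws, "rhat") <- rhat
  attr(draws, "chains") <- chains
  attr(draws, "n_warmup") <- n_warmup
  attr(draws, "step_size") <- vapply(res, `[[`, numeric(1), "step_size")
  draws
}
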