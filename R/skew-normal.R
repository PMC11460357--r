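# Skew-normal SN(xi, omega, alpha) in the standard location/scale/shape
# parameterization: density 2/omega * phi(z) * Phi(alpha * z), z = (x - xi)/omega.

#' Skew-normal density, sampler, and moments
#'
#' Standard three-parameter skew normal SN(xi, omega, alpha) used for
#' per-sharer follower-ideology profiles: `xi` is location, `omega > 0` scale,
#' and `alpha` shape (alpha = 0 recovers the normal distribution; positive
#' alpha skews right).
#'
#' @param x Numeric vector of quantiles.
#' @param n Number of draws.
#' @param xi,omega,alpha Location, scale (> 0), and shape parameters.
#' @param log Return the log density?
#'
#' @return `dskewnorm()` a numeric vector of densities; `rskewnorm()` a numeric
#'   vector of `n` draws; `skewnorm_moments()` a list with elements `mean`,
#'   `sd`, and `skewness` (closed form).
#'
#' @examples
#' dskewnorm(0, 0, 1, 0) == dnorm(0)
#' skewnorm_moments(0, 1, 0)$mean
#' @export
dskewnorm <- function(x, xi, omega, alpha, log = FALSE) {
  if (any(omega <= 0)) abort("`omega` must be > 0.",
                             class = "receptr_validation_error")
  z <- (x - xi) / omega
  lp <- log(2) - log(omega) + dnorm(z, log = TRUE) +
    pnorm(alpha * z, log.p = TRUE)
  if (log) lp else exp(lp)
}

#' @rdname dskewnorm
#' @export
rskewnorm <- function(n, xi, omega, alpha) {
  if (any(omega <= 0)) abort("`omega` must be > 0.",
                             class = "receptr_validation_error")
  if (n < 0) abort("`n` must be >= 0.", class = "receptr_validation_error")
  if (n == 0) return(numeric(0))
  # Conditioning representation: delta*|z0| + sqrt(1 - delta^2)*z1 is SN(0,1,alpha).
  delta <- alpha / sqrt(1 + alpha^2)
  z0 <- rnorm(n)
  z1 <- rnorm(n)
  xi + omega * (delta * abs(z0) + sqrt(1 - delta^2) * z1)
}

#' @rdname dskewnorm
#' @export
skewnorm_moments <- function(xi, omega, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  mu_z <- delta * sqrt(2 / pi)
  m <- xi + omega * mu_z
  v <- omega^2 * (1 - mu_z^2)
  g1 <- (4 - pi) / 2 * mu_z^3 / (1 - mu_z^2)^(3 / 2)
  list(mean = m, sd = sqrt(v), skewness = g1)
}

# phi(x)/Phi(x), computed in log space to survive far-left tails.
mills_ratio <- function(x) {
  exp(dnorm(x, log = TRUE) - pnorm(x, log.p = TRUE))
}

# Inverse-CDF sampler for Normal(mean, sd) truncated to [lower, Inf); used for
# both viewing delays and zero-truncated scale priors so draws are seed-stable.
rtruncnorm_inv <- function(n, mean, sd, lower = 0) {
  if (sd <= 0) abort("`sd` must be > 0.", class = "receptr_validation_error")
  if (n < 0) abort("`n` must be >= 0.", class = "receptr_validation_error")
  if (n == 0) return(numeric(0))
  p_lo <- pnorm(lower, mean, sd)
  u <- runif(n, p_lo, 1)
  qnorm(u, mean, sd)
}

truncnorm_mean <- function(mean, sd, lower = 0) {
  a <- (lower - mean) / sd
  mean + sd * dnorm(a) / (1 - pnorm(a))
}
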