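# Two-stage Bayesian ideology model: a population-level normal fitted to all
# known scores, then a per-sharer skew normal over that sharer's scored
# followers with the population posterior propagated as prior. Continuous
# scores (negative = left-leaning, positive = right-leaning) map onto the
# seven ordered survey categories via fixed, evenly sized bins.

IDEOLOGY_BREAKS <- c(-Inf, -2.5, -1.5, -0.5, 0.5, 1.5, 2.5, Inf)

#' Ordered ideology categories
#'
#' The seven survey categories, ordered left to right.
#'
#' @return Character vector of the 7 category labels.
#' @export
ideology_categories <- function() {
  c("Very Liberal", "Liberal", "Somewhat Liberal", "Moderate",
    "Somewhat Conservative", "Conservative", "Very Conservative")
}

#' Map continuous ideology scores to survey categories
#'
#' Bins are left-open and right-closed, half-unit-centred and evenly sized:
#' Moderate is (-0.5, 0.5], Conservative is (1.5, 2.5], scores above 2.5 are
#' Very Conservative and scores at or below -2.5 are Very Liberal. Every
#' finite score maps to exactly one category.
#'
#' @param score Numeric vector of continuous ideology scores.
#' @return Ordered factor with the 7 levels of [ideology_categories()].
#' @examples
#' bin_score(c(0, 2.5, -0.5))
#' @export
bin_score <- function(score) {
  if (!is.numeric(score)) {
    abort("`score` must be numeric.", class = "receptr_validation_error")
  }
  if (any(!is.finite(score))) {
    abort("All scores must be finite.", class = "receptr_validation_error")
  }
  cut(score, breaks = IDEOLOGY_BREAKS, labels = ideology_categories(),
      right = TRUE, ordered_result = TRUE)
}

# -------------------------------------------------------------------------
# Population-level fit

#' Fit the population ideology distribution
#'
#' Fits Normal(mu_pop, sigma_pop) to known ideology scores by NUTS, with a
#' Normal(0, 2) prior on the mean and an Exponential(rate = 2) prior on the
#' standard deviation. Samples larger than `max_n` are subsampled without
#' replacement under the run seed.
#'
#' @param scores Numeric vector of scores, or a data frame with a `score`
#'   column.
#' @param chains,warmup,draws MCMC settings (total retained draws across
#'   chains).
#' @param max_n Cap on the number of scores used (default 500,000).
#' @param min_n Minimum observations required (default 10).
#' @param seed Optional integer seed.
#' @param divergence_warn_rate Warn when the divergent-transition fraction
#'   exceeds this threshold.
#'
#' @return A `population_prior` object: posterior draws of `mu_pop` and
#'   `sigma_pop` with sampler diagnostics. Use [tidy()] / [glance()] to
#'   summarise.
#' @export
fit_population_prior <- function(scores, chains = 2, warmup = 1000,
                                 draws = 3000, max_n = 500000, min_n = 10,
                                 seed = NULL, divergence_warn_rate = 0.02) {
  if (is.data.frame(scores)) {
    assert_columns(scores, "score", "scores")
    scores <- scores$score
  }
  scores <- scores[!is.na(scores)]
  if (any(!is.finite(scores))) {
    abort("Ideology scores must be finite.",
          class = "receptr_validation_error")
  }
  if (length(scores) < min_n) {
    abort(sprintf("Need at least %d scores to fit the population model (got %d).",
                  min_n, length(scores)),
          class = "receptr_insufficient_data")
  }
  n_total <- length(scores)
  if (n_total > max_n) {
    scores <- with_seed_or_current(derive_seed(seed, 1L),
                                   sample(scores, max_n, replace = FALSE))
  }
  n <- length(scores)
  sy <- sum(scores)
  syy <- sum(scores^2)
  # Unconstrained parameters (mu, log sigma); Jacobian term + log sigma.
  logp <- function(th) {
    mu <- th[1]; ls <- th[2]; s2 <- exp(2 * ls)
    -n * ls - 0.5 * (syy - 2 * mu * sy + n * mu^2) / s2 +
      dnorm(mu, 0, 2, log = TRUE) - 2 * exp(ls) + ls
  }
  grad <- function(th) {
    mu <- th[1]; ls <- th[2]; s <- exp(ls); s2 <- s * s
    q <- syy - 2 * mu * sy + n * mu^2
    c((sy - n * mu) / s2 - mu / 4,
      -n + q / s2 - 2 * s + 1)
  }
  init <- c(mean(scores), log(max(sd(scores), 1e-3)))
  mat <- nuts_sample(logp, grad, init, chains = chains, n_warmup = warmup,
                     n_draws_total = draws, seed = derive_seed(seed, 2L),
                     param_names = c("mu", "log_sigma"))
  div <- attr(mat, "divergences")
  if (div / nrow(mat) > divergence_warn_rate) {
    warn(sprintf("Population fit: %d divergent transitions (%.1f%% of draws).",
                 div, 100 * div / nrow(mat)))
  }
  out <- structure(
    list(draws = tibble(mu_pop = mat[, "mu"], sigma_pop = exp(mat[, "log_sigma"])),
         n_obs = n, n_supplied = n_total,
         diagnostics = list(divergences = div, rhat = attr(mat, "rhat"),
                            step_size = attr(mat, "step_size")),
         sampler = list(chains = chains, warmup = warmup, draws = nrow(mat)),
         seed = seed),
    class = "population_prior")
  out
}

#' @export
print.population_prior <- function(x, ...) {
  cat("<population_prior>\n")
  cat(sprintf("  fitted on %d scores (%d supplied)\n", x$n_obs, x$n_supplied))
  cat(sprintf("  mu_pop    %.3f (sd %.3f)\n", mean(x$draws$mu_pop),
              sd(x$draws$mu_pop)))
  cat(sprintf("  sigma_pop %.3f (sd %.3f)\n", mean(x$draws$sigma_pop),
              sd(x$draws$sigma_pop)))
  cat(sprintf("  %d draws, %d chains, %d divergences\n",
              nrow(x$draws), x$sampler$chains, x$diagnostics$divergences))
  invisible(x)
}

#' @rdname fit_population_prior
#' @param x A `population_prior` object.
#' @param ... Unused.
#' @export
tidy.population_prior <- function(x, ...) {
  d <- x$draws
  tibble(
    term = c("mu_pop", "sigma_pop"),
    estimate = c(mean(d$mu_pop), mean(d$sigma_pop)),
    std.error = c(sd(d$mu_pop), sd(d$sigma_pop)),
    conf.low = c(quantile(d$mu_pop, 0.025), quantile(d$sigma_pop, 0.025)),
    conf.high = c(quantile(d$mu_pop, 0.975), quantile(d$sigma_pop, 0.975))
  )
}

#' @rdname fit_population_prior
#' @export
glance.population_prior <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_draws = nrow(x$draws), chains = x$sampler$chains,
         divergences = x$diagnostics$divergences,
         max_rhat = max(x$diagnostics$rhat))
}

# Prior hyperparameters propagated from the population posterior. A sharer's
# follower-location mu_i is assumed to vary across sharers with the
# population's ideological spread, so its prior is Normal(E[mu_pop],
# E[sigma_pop]); the follower-scale sigma_i gets a zero-truncated normal
# centred on E[sigma_pop] with scale E[sigma_pop]/2. Centring on the
# population posterior keeps zero-data sharers at the population distribution,
# while the population-spread prior width leaves the per-sharer likelihood in
# charge whenever followers carry real information. (Using the Monte-Carlo
# uncertainty of mu_pop as the prior width instead would pin every sharer at
# the population mean once the population sample is large.)
population_hyperpars <- function(pop) {
  stopifnot(inherits(pop, "population_prior"))
  m_sigma <- mean(pop$draws$sigma_pop)
  list(m_mu = mean(pop$draws$mu_pop), s_mu = m_sigma,
       m_sigma = m_sigma, s_sigma = m_sigma / 2)
}

# -------------------------------------------------------------------------
# Per-sharer skew-normal fit

#' Fit a sharer's follower-ideology distribution
#'
#' Fits SN(mu_i, sigma_i, alpha_i) to the known ideology scores among one
#' sharer's followers, by NUTS. The population posterior is propagated as the
#' prior: mu_i gets a normal prior moment-matched to the mu_pop draws, sigma_i
#' a zero-truncated normal moment-matched to the sigma_pop draws, and the
#' shape alpha_i a Normal(0, 1) prior (followers most likely resemble a normal
#' distribution, skewing left or right with equal prior probability). With no
#' scored followers the model falls back to the prior itself with alpha fixed
#' at 0, so that sharer's followers are assumed to match the population.
#'
#' @param scored_follower_values Numeric vector of known follower scores
#'   (possibly empty).
#' @param pop A fitted [fit_population_prior()] object.
#' @param user_id Optional sharer identifier carried through to the result.
#' @param chains,warmup,draws MCMC settings (total retained draws).
#' @param seed Optional integer seed.
#' @param divergence_warn_rate Warn above this divergent fraction.
#'
#' @return A `follower_ideology_model`: posterior (or prior) draws of `mu_i`,
#'   `sigma_i`, `alpha_i`, the scored-follower count, and a `fallback` flag.
#' @export
fit_follower_distribution <- function(scored_follower_values, pop,
                                      user_id = NA_character_, chains = 4,
                                      warmup = 500, draws = 2000, seed = NULL,
                                      divergence_warn_rate = 0.02) {
  stopifnot(inherits(pop, "population_prior"))
  y <- scored_follower_values
  if (length(y) > 0 && any(!is.finite(y))) {
    abort("Follower scores must be finite.",
          class = "receptr_validation_error")
  }
  hp <- population_hyperpars(pop)

  if (length(y) == 0) {
    # Zero-data fallback: prior-predictive draws for location/scale, alpha = 0.
    prior_draws <- with_seed_or_current(derive_seed(seed, 3L), {
      tibble(mu_i = rnorm(draws, hp$m_mu, hp$s_mu),
             sigma_i = rtruncnorm_inv(draws, hp$m_sigma, hp$s_sigma, lower = 0),
             alpha_i = rep(0, draws))
    })
    return(structure(
      list(user_id = user_id, draws = prior_draws, n_scored_followers = 0L,
           fallback = TRUE, hyperpars = hp,
           diagnostics = list(divergences = 0L, rhat = c(mu = NA, log_sigma = NA,
                                                         alpha = NA)),
           sampler = list(chains = 0L, warmup = 0L, draws = draws),
           seed = seed),
      class = "follower_ideology_model"))
  }

  n <- length(y)
  # Unconstrained (xi, log omega, alpha); truncated-normal prior on omega plus
  # Jacobian; the truncation constant does not depend on parameters.
  logp <- function(th) {
    xi <- th[1]; lo <- th[2]; a <- th[3]; om <- exp(lo)
    z <- (y - xi) / om
    n * log(2) - n * lo + sum(dnorm(z, log = TRUE)) +
      sum(pnorm(a * z, log.p = TRUE)) +
      dnorm(xi, hp$m_mu, hp$s_mu, log = TRUE) +
      dnorm(om, hp$m_sigma, hp$s_sigma, log = TRUE) + lo +
      dnorm(a, 0, 1, log = TRUE)
  }
  grad <- function(th) {
    xi <- th[1]; lo <- th[2]; a <- th[3]; om <- exp(lo)
    z <- (y - xi) / om
    mr <- mills_ratio(a * z)
    dxi <- sum(z) / om - (a / om) * sum(mr) - (xi - hp$m_mu) / hp$s_mu^2
    dlo <- -n + sum(z^2) - a * sum(z * mr) -
      om * (om - hp$m_sigma) / hp$s_sigma^2 + 1
    da <- sum(z * mr) - a
    c(dxi, dlo, da)
  }
  init <- c(mean(y), log(max(sd(y), hp$m_sigma / 10, 1e-3)), 0)
  if (n == 1) init <- c(y, log(hp$m_sigma), 0)
  mat <- nuts_sample(logp, grad, init, chains = chains, n_warmup = warmup,
                     n_draws_total = draws, seed = derive_seed(seed, 4L),
                     param_names = c("mu", "log_sigma", "alpha"),
                     target_accept = 0.9)
  div <- attr(mat, "divergences")
  if (div / nrow(mat) > divergence_warn_rate) {
    warn(sprintf("Follower fit (%s): %d divergent transitions.", user_id, div))
  }
  structure(
    list(user_id = user_id,
         draws = tibble(mu_i = mat[, "mu"], sigma_i = exp(mat[, "log_sigma"]),
                        alpha_i = mat[, "alpha"]),
         n_scored_followers = n, fallback = FALSE, hyperpars = hp,
         diagnostics = list(divergences = div, rhat = attr(mat, "rhat")),
         sampler = list(chains = chains, warmup = warmup, draws = nrow(mat)),
         seed = seed),
    class = "follower_ideology_model")
}

#' @export
print.follower_ideology_model <- function(x, ...) {
  cat("<follower_ideology_model>",
      if (x$fallback) "(population fallback)" else "", "\n")
  cat(sprintf("  sharer: %s, scored followers: %d\n", x$user_id,
              x$n_scored_followers))
  cat(sprintf("  mu_i %.3f  sigma_i %.3f  alpha_i %.3f (posterior means)\n",
              mean(x$draws$mu_i), mean(x$draws$sigma_i),
              mean(x$draws$alpha_i)))
  invisible(x)
}

#' @rdname fit_follower_distribution
#' @param x A `follower_ideology_model` object.
#' @param ... Unused.
#' @export
tidy.follower_ideology_model <- function(x, ...) {
  d <- x$draws
  tibble(
    term = c("mu_i", "sigma_i", "alpha_i"),
    estimate = vapply(d, mean, numeric(1), USE.NAMES = FALSE),
    std.error = vapply(d, sd, numeric(1), USE.NAMES = FALSE),
    conf.low = vapply(d, quantile, numeric(1), probs = 0.025,
                      USE.NAMES = FALSE),
    conf.high = vapply(d, quantile, numeric(1), probs = 0.975,
                       USE.NAMES = FALSE)
  )
}

#' @rdname fit_follower_distribution
#' @export
glance.follower_ideology_model <- function(x, ...) {
  tibble(user_id = x$user_id, n_scored_followers = x$n_scored_followers,
         fallback = x$fallback, n_draws = nrow(x$draws),
         divergences = x$diagnostics$divergences)
}

#' Draw ideology scores for unscored followers
#'
#' Draws `n` independent scores from a sharer's fitted follower distribution,
#' by default a skew normal at the posterior-mean parameters. With
#' `posterior_predictive = TRUE` each draw first samples a posterior draw of
#' (mu_i, sigma_i, alpha_i), giving full posterior-predictive uncertainty.
#'
#' @param model A [fit_follower_distribution()] result.
#' @param n Number of scores to draw (>= 0).
#' @param seed Optional integer seed.
#' @param posterior_predictive Integrate over posterior parameter draws?
#' @return Numeric vector of `n` scores.
#' @export
sample_missing_follower_scores <- function(model, n, seed = NULL,
                                           posterior_predictive = FALSE) {
  stopifnot(inherits(model, "follower_ideology_model"))
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0) {
    abort("`n` must be a single count >= 0.",
          class = "receptr_validation_error")
  }
  n <- as.integer(n)
  if (n == 0) return(numeric(0))
  with_seed_or_current(seed, {
    if (posterior_predictive) {
      idx <- sample.int(nrow(model$draws), n, replace = TRUE)
      d <- model$draws[idx, ]
      rskewnorm(n, d$mu_i, d$sigma_i, d$alpha_i)
    } else {
      rskewnorm(n, mean(model$draws$mu_i), mean(model$draws$sigma_i),
                mean(model$draws$alpha_i))
    }
  })
}

# -------------------------------------------------------------------------
# Sharer-score imputation

#' Impute ideology scores for article sharers
#'
#' Sharers keep their known score when one exists; otherwise the score is the
#' arithmetic mean of their friends' known scores; sharers with no known score
#' and no scored friends fall back to the population posterior mean and are
#' flagged.
#'
#' @param user_id Character vector of sharer ids.
#' @param known_scores Data frame with columns `user_id`, `score` (the partial
#'   score table).
#' @param graph A [social_graph()].
#' @param pop A fitted [fit_population_prior()] object (used only for the
#'   fallback).
#' @return Tibble with columns `user_id`, `score`, `method` (one of "known",
#'   "friend_mean", "population").
#' @export
impute_tweeter_score <- function(user_id, known_scores, graph, pop) {
  assert_columns(known_scores, c("user_id", "score"), "known_scores")
  stopifnot(inherits(graph, "social_graph"))
  score_map <- setNames(known_scores$score, known_scores$user_id)
  pop_mean <- mean(pop$draws$mu_pop)
  res <- purrr::map(unique(as.character(user_id)), function(u) {
    if (!is.na(score_map[u])) {
      return(list(u, unname(score_map[u]), "known"))
    }
    fr <- friends(graph, u)
    fr_scores <- score_map[fr]
    fr_scores <- fr_scores[!is.na(fr_scores)]
    if (length(fr_scores) > 0) {
      list(u, mean(fr_scores), "friend_mean")
    } else {
      list(u, pop_mean, "population")
    }
  })
  out <- tibble(
    user_id = vapply(res, function(r) r[[1]], character(1)),
    score = vapply(res, function(r) r[[2]], numeric(1)),
    method = vapply(res, function(r) r[[3]], character(1))
  )
  n_fb <- sum(out$method == "population")
  if (n_fb > 0) {
    inform(sprintf(
      "impute_tweeter_score: %d sharer(s) had no score and no scored friends; population-mean fallback used.",
      n_fb))
  }
  out
}
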