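# Score binning, sharer imputation, and the two-stage Bayesian model.

test_that("bins match the published mapping, including boundaries", {
  expect_equal(as.character(bin_score(0)), "Moderate")
  expect_equal(as.character(bin_score(2.5)), "Conservative")
  expect_equal(as.character(bin_score(-0.5)), "Somewhat Liberal")
  expect_equal(as.character(bin_score(2.500001)), "Very Conservative")
  expect_equal(as.character(bin_score(-2.5)), "Very Liberal")
  expect_error(bin_score(NaN), class = "receptr_validation_error")
  expect_error(bin_score(Inf), class = "receptr_validation_error")
})

test_that("bins partition the real line and are idempotent at midpoints", {
  set.seed(11)
  x <- c(runif(2000, -8, 8), seq(-3.5, 3.5, by = 0.25))
  cats <- bin_score(x)
  expect_false(any(is.na(cats)))
  expect_equal(length(levels(cats)), 7)
  expect_true(is.ordered(cats))
  # Category midpoints re-bin to themselves.
  mids <- c(-3, -2, -1, 0, 1, 2, 3)
  expect_equal(as.character(bin_score(mids)), ideology_categories())
})

test_that("sharer imputation: pass-through, friend mean, population fallback", {
  g <- graph_from_spec(c("u1->f1", "u1->f2", "u1->f3", "u2->f9"))
  known <- tibble::tibble(user_id = c("u0", "f1", "f2", "f3"),
                          score = c(1.3, -1, 0, 2))
  set.seed(21)
  pop <- fit_population_prior(rnorm(2000, 0.4, 1), warmup = 200, draws = 400,
                              seed = 5)
  res <- suppressMessages(
    impute_tweeter_score(c("u0", "u1", "u2"), known, g, pop))
  expect_equal(res$score[res$user_id == "u0"], 1.3)
  expect_equal(res$method[res$user_id == "u0"], "known")
  expect_equal(res$score[res$user_id == "u1"], mean(c(-1, 0, 2)))
  expect_equal(res$method[res$user_id == "u1"], "friend_mean")
  # No score, no scored friends: population posterior mean, flagged.
  expect_equal(res$score[res$user_id == "u2"], mean(pop$draws$mu_pop))
  expect_equal(res$method[res$user_id == "u2"], "population")
})

test_that("population fit recovers generating parameters and caps the sample", {
  set.seed(31)
  y <- rnorm(10000, 0.3, 1.2)
  pop <- fit_population_prior(y, seed = 7)
  td <- tidy(pop)
  mu_hat <- td$estimate[td$term == "mu_pop"]
  mu_sd <- td$std.error[td$term == "mu_pop"]
  sg_hat <- td$estimate[td$term == "sigma_pop"]
  sg_sd <- td$std.error[td$term == "sigma_pop"]
  expect_lt(abs(mu_hat - 0.3), 3 * mu_sd)
  expect_lt(abs(sg_hat - 1.2), 3 * sg_sd)
  expect_equal(nrow(pop$draws), 3000)
  expect_true(all(pop$draws$sigma_pop > 0))
  expect_true(all(glance(pop)$max_rhat < 1.05))

  # Oversized samples are subsampled to the cap, deterministically per seed.
  pop_a <- fit_population_prior(rnorm(1200, 0, 1), max_n = 1000,
                                warmup = 200, draws = 400, seed = 9)
  pop_b <- fit_population_prior(rnorm(1200, 0, 1), max_n = 1000,
                                warmup = 200, draws = 400, seed = 9)
  expect_equal(pop_a$n_obs, 1000)
  expect_equal(pop_a$n_supplied, 1200)
  expect_error(fit_population_prior(rnorm(5), seed = 1),
               class = "receptr_insufficient_data")
})

test_that("degenerate all-equal data concentrates mu at the value", {
  pop <- fit_population_prior(rep(0, 50), warmup = 300, draws = 600, seed = 3)
  expect_lt(abs(mean(pop$draws$mu_pop)), 0.05)
  expect_lt(quantile(pop$draws$sigma_pop, 0.5), 0.1)
})

test_that("follower fit recovers skew-normal parameters within 3 posterior SDs", {
  set.seed(41)
  pop <- fit_population_prior(rnorm(5000, 0, 1.5), warmup = 300, draws = 600,
                              seed = 2)
  y <- rskewnorm(1000, xi = 0.5, omega = 1.0, alpha = 2.0)
  fit <- fit_follower_distribution(y, pop, user_id = "u1", seed = 17)
  td <- tidy(fit)
  truth <- c(mu_i = 0.5, sigma_i = 1.0, alpha_i = 2.0)
  for (term in names(truth)) {
    est <- td$estimate[td$term == term]
    se <- td$std.error[td$term == term]
    expect_lt(abs(est - truth[[term]]), 3 * se)
  }
  expect_false(fit$fallback)
  expect_equal(fit$n_scored_followers, 1000)
  expect_equal(nrow(fit$draws), 2000)
})

test_that("zero-data fallback reproduces the prior", {
  set.seed(51)
  pop <- fit_population_prior(rnorm(5000, 0.2, 1.1), warmup = 300,
                              draws = 600, seed = 2)
  hp <- receptr:::population_hyperpars(pop)
  fit <- fit_follower_distribution(numeric(0), pop, user_id = "lonely",
                                   draws = 2000, seed = 19)
  expect_true(fit$fallback)
  expect_equal(fit$n_scored_followers, 0L)
  expect_true(all(fit$draws$alpha_i == 0))
  # Location draws match the moment-matched prior (mu_pop posterior moments).
  expect_lt(abs(mean(fit$draws$mu_i) - hp$m_mu), 4 * hp$s_mu / sqrt(2000))
  expect_lt(abs(sd(fit$draws$mu_i) - hp$s_mu), 0.1 * hp$s_mu)
  expect_true(all(fit$draws$sigma_i > 0))
  # KS check against the analytic prior for the location parameter.
  ks <- suppressWarnings(
    stats::ks.test(fit$draws$mu_i, "pnorm", hp$m_mu, hp$s_mu))
  expect_gt(ks$p.value, 0.001)
})

test_that("posterior uncertainty shrinks as the scored-follower count grows", {
  set.seed(61)
  pop <- fit_population_prior(rnorm(5000, 0, 1.5), warmup = 300, draws = 600,
                              seed = 2)
  widths <- vapply(c(10, 100, 1000), function(n) {
    y <- rskewnorm(n, xi = 0, omega = 1, alpha = 1)
    fit <- fit_follower_distribution(y, pop, chains = 2, warmup = 300,
                                     draws = 800, seed = n)
    sd(fit$draws$mu_i)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("missing-score sampling is seeded, sized, and moment-correct", {
  set.seed(71)
  pop <- fit_population_prior(rnorm(2000, 0, 1), warmup = 200, draws = 400,
                              seed = 2)
  fit <- fit_follower_distribution(numeric(0), pop, draws = 500, seed = 3)
  expect_identical(sample_missing_follower_scores(fit, 0, seed = 1),
                   numeric(0))
  expect_error(sample_missing_follower_scores(fit, -1),
               class = "receptr_validation_error")
  a <- sample_missing_follower_scores(fit, 100, seed = 42)
  b <- sample_missing_follower_scores(fit, 100, seed = 42)
  expect_identical(a, b)

  # Moments at the posterior-mean parameters (alpha = 0 here).
  big <- sample_missing_follower_scores(fit, 50000, seed = 8)
  mom <- skewnorm_moments(mean(fit$draws$mu_i), mean(fit$draws$sigma_i), 0)
  expect_lt(abs(mean(big) - mom$mean), 0.02 * max(1, abs(mom$mean)) + 0.02)
  skew <- mean((big - mean(big))^3) / sd(big)^3
  expect_lt(abs(skew), 0.05)
})

test_that("skew-normal sampler matches closed-form moments for alpha != 0", {
  set.seed(81)
  x <- rskewnorm(200000, xi = 1, omega = 2, alpha = 3)
  mom <- skewnorm_moments(1, 2, 3)
  expect_lt(abs(mean(x) - mom$mean), 0.02)
  expect_lt(abs(sd(x) - mom$sd), 0.02)
  skew <- mean((x - mean(x))^3) / sd(x)^3
  expect_lt(abs(skew - mom$skewness), 0.03)
  # Density integrates to moments too: cross-check against numeric integral.
  m_num <- stats::integrate(function(t) t * dskewnorm(t, 1, 2, 3),
                            -Inf, Inf)$value
  expect_equal(m_num, mom$mean, tolerance = 1e-6)
})

test_that("NUTS posterior agrees with an independent Gibbs sampler (rjags)", {
  set.seed(91)
  y <- rnorm(800, 0.5, 0.9)
  pop <- fit_population_prior(y, warmup = 500, draws = 2000, seed = 13)
  model_str <- "
    model {
      for (i in 1:n) { y[i] ~ dnorm(mu, tau) }
      mu ~ dnorm(0, 0.25)
      sigma ~ dexp(2)
      tau <- pow(sigma, -2)
    }"
  jm <- rjags::jags.model(textConnection(model_str),
                          data = list(y = y, n = length(y)),
                          n.chains = 2, quiet = TRUE,
                          inits = list(.RNG.name = "base::Wichmann-Hill",
                                       .RNG.seed = 7))
  stats::update(jm, 500, progress.bar = "none")
  js <- rjags::coda.samples(jm, c("mu", "sigma"), n.iter = 2000,
                            progress.bar = "none")
  jdraws <- as.matrix(js)
  expect_lt(abs(mean(pop$draws$mu_pop) - mean(jdraws[, "mu"])),
            3 * sd(jdraws[, "mu"]) / 10)
  expect_lt(abs(mean(pop$draws$sigma_pop) - mean(jdraws[, "sigma"])),
            3 * sd(jdraws[, "sigma"]) / 10)
  expect_lt(abs(sd(pop$draws$mu_pop) / sd(jdraws[, "mu"]) - 1), 0.25)
})
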