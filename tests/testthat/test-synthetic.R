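# The synthetic generator: graph homophily, cascades, surveys, demo bundles.

test_that("config validation catches bad weights and probabilities", {
  expect_error(synthetic_config(ideology_weights = c(0.5, 0.2, 0.2)),
               class = "receptr_validation_error")
  expect_error(synthetic_config(homophily = -1),
               class = "receptr_validation_error")
  expect_error(synthetic_config(observability = 1.5),
               class = "receptr_validation_error")
})

test_that("zero homophily makes following independent of ideological distance", {
  cfg <- synthetic_config(n_users = 2000, homophily = 0, seed = 14)
  net <- generate_social_graph(cfg)
  scores <- setNames(net$truth$score, net$truth$user_id)
  edges <- net$graph$edges
  d_edge <- abs(scores[edges$follower_id] - scores[edges$followee_id])
  # Null distances: random user pairs.
  set.seed(15)
  i <- sample(net$truth$user_id, 20000, replace = TRUE)
  j <- sample(net$truth$user_id, 20000, replace = TRUE)
  d_null <- abs(scores[i] - scores[j])[i != j]
  # Chi-squared on edge-distance counts across the null's deciles.
  breaks <- unique(quantile(d_null, seq(0, 1, 0.1)))
  obs <- table(cut(d_edge, breaks, include.lowest = TRUE))
  expf <- diff(stats::ecdf(d_null)(breaks)) * length(d_edge)
  chi2 <- sum((as.numeric(obs) - expf)^2 / expf)
  pval <- stats::pchisq(chi2, df = length(obs) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.001)
})

test_that("strong homophily shortens ideological distance along edges", {
  cfg <- synthetic_config(n_users = 1500, homophily = 3, seed = 16)
  net <- generate_social_graph(cfg)
  scores <- setNames(net$truth$score, net$truth$user_id)
  edges <- net$graph$edges
  d_edge <- mean(abs(scores[edges$follower_id] - scores[edges$followee_id]))
  set.seed(17)
  i <- sample(net$truth$user_id, 20000, replace = TRUE)
  j <- sample(net$truth$user_id, 20000, replace = TRUE)
  d_pop <- mean(abs(scores[i] - scores[j])[i != j])
  expect_lt(d_edge, d_pop)
})

test_that("observability controls which scores are emitted", {
  cfg <- synthetic_config(n_users = 300, observability = 1, seed = 18)
  net <- generate_social_graph(cfg)
  expect_equal(nrow(net$known_scores), 300)
  cfg0 <- synthetic_config(n_users = 300, observability = 0, seed = 18)
  expect_equal(nrow(generate_social_graph(cfg0)$known_scores), 0)
})

test_that("cascades honour the retweet probability and ground truth", {
  cfg <- synthetic_config(n_users = 300, retweet_prob = 0, n_seed_sharers = 4,
                          seed = 19)
  net <- generate_social_graph(cfg)
  ci <- generate_cascades(net, cfg)
  expect_equal(nrow(ci$tweets), 4)
  expect_true(all(ci$tweets$kind == "original"))

  cfg2 <- synthetic_config(n_users = 300, retweet_prob = 0.5,
                           degree_exponent = 2.0, seed = 20)
  net2 <- generate_social_graph(cfg2)
  ci2 <- generate_cascades(net2, cfg2)
  expect_gt(nrow(ci2$tweets), 4)
  # Ground-truth parents exist and precede their children.
  tp <- ci2$true_parents
  tt <- setNames(ci2$tweets$time, ci2$tweets$tweet_id)
  nonroot <- tp[!is.na(tp$true_parent_tweet_id), ]
  expect_true(all(tt[nonroot$true_parent_tweet_id] < tt[nonroot$tweet_id]))
  # Users tweet at most once per article.
  dup <- dplyr::count(ci2$tweets, article_id, user_id)
  expect_true(all(dup$n == 1))
})

test_that("reconstruction recovers most true parents on a fully observed graph", {
  cfg <- synthetic_config(n_users = 800, retweet_prob = 0.4,
                          degree_exponent = 2.0, observability = 1,
                          max_generations = 6, seed = 23)
  net <- generate_social_graph(cfg)
  ci <- generate_cascades(net, cfg)
  retweets <- sum(ci$tweets$kind != "original")
  expect_gt(retweets, 20)
  casc <- build_cascades(ci$tweets, net$graph)
  joined <- merge(as.data.frame(casc), ci$true_parents, by = "tweet_id")
  joined <- joined[joined$kind != "original", ]
  recovered <- mean(joined$parent_tweet_id == joined$true_parent_tweet_id)
  expect_gte(recovered, 0.6)
})

test_that("survey generation is balanced and recovers the generating rates", {
  articles <- tibble::tibble(article_id = "a1", slant = 0.5, quality = 0.6)
  cfg <- synthetic_config(n_respondents = 70, seed = 24)
  out <- generate_survey(articles, cfg)
  counts <- table(out$responses$category)
  expect_true(all(abs(counts - 10) <= 1))

  # Large panel: estimated p within binomial tolerance of the truth.
  cfg_big <- synthetic_config(n_respondents = 14000, seed = 25)
  big <- generate_survey(articles, cfg_big)
  bt <- compute_belief_table(big$responses)
  joined <- merge(as.data.frame(bt), big$truth, by = c("article_id",
                                                       "category"))
  expect_true(all(abs(joined$p - joined$p_true) < 0.02))

  # Degenerate all-believe case.
  cfg_sure <- synthetic_config(n_respondents = 140, belief_intercept = 50,
                               seed = 26)
  sure <- generate_survey(articles, cfg_sure)
  expect_true(all(sure$responses$rating == "true"))
})

test_that("demo bundles are deterministic under seed and load cleanly", {
  d1 <- make_demo_dataset("tiny", seed = 4, dir = tempfile())
  d2 <- make_demo_dataset("tiny", seed = 4, dir = tempfile())
  for (f in c("tweets", "edges", "scores", "survey", "articles")) {
    expect_identical(readLines(d1[[f]]), readLines(d2[[f]]),
                     info = f)
  }
  data <- load_dataset(dirname(d1$tweets))
  expect_s3_class(data$graph, "social_graph")
  expect_gt(nrow(data$tweets), 0)
  casc <- build_cascades(data$tweets, data$graph)
  expect_true(validate_cascades(casc))
})

test_that("end-to-end recovery: r equals the sum of true belief over exposed users", {
  # Full observability and ground-truth p: with near-zero delays, r_j must
  # equal the sum of each truly exposed user's true belief probability.
  cfg <- synthetic_config(n_users = 400, retweet_prob = 0.3,
                          degree_exponent = 2.0, observability = 1,
                          seed = 27)
  net <- generate_social_graph(cfg)
  ci <- generate_cascades(net, cfg)
  casc <- build_cascades(ci$tweets, net$graph)
  scores <- net$truth[, c("user_id", "score")]
  m <- delay_model(mu = 1e-6, sigma = 1e-6)
  ev <- compute_exposures(casc, net$graph, scores, model = m, seed = 31)
  belief <- generate_survey(
    tibble::tibble(article_id = "a001", slant = 0.2, quality = 0.5),
    synthetic_config(seed = 28))$truth
  belief <- dplyr::rename(belief, p = "p_true")
  est <- estimate_receptivity(tabulate_exposures(ev), belief)
  manual <- ev %>%
    dplyr::mutate(category = as.character(category)) %>%
    dplyr::left_join(belief, by = c("article_id", "category")) %>%
    dplyr::summarise(r = sum(p))
  expect_equal(glance(est)$r, manual$r, tolerance = 1e-9)
})
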