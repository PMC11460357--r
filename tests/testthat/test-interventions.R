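# Cascade pruning, belief discounting, and replicated intervention runs.

chain_cascade <- function() {
  g <- graph_from_spec(c("B->orig", "C->B", "D->C"))
  tweets <- dplyr::bind_rows(
    tweet_row("t1", "orig", 0),
    tweet_row("t2", "B", 1, "retweet", "t1"),
    tweet_row("t3", "C", 2, "retweet", "t1"),
    tweet_row("t4", "D", 3, "retweet", "t1"))
  build_cascades(tweets, g)
}

test_that("pruning respects probability endpoints and subtree semantics", {
  casc <- chain_cascade()
  expect_identical(prune_cascade(casc, 0, 0, seed = 1), casc)
  only_orig <- prune_cascade(casc, 1, 0, seed = 1)
  expect_equal(only_orig$tweet_id, "t1")
  # Originals are never removed even at prob 1.
  expect_true(all(only_orig$kind == "original"))
  # Removing B (t2) must drop its descendants C and D.
  set.seed(42)
  found <- FALSE
  for (s in 1:200) {
    surv <- prune_cascade(casc, 0.5, 0, seed = s)
    ids <- surv$tweet_id
    if (!"t2" %in% ids) {
      found <- TRUE
      expect_false("t3" %in% ids)
      expect_false("t4" %in% ids)
    }
    # Survivors always form a valid forest; pruning creates no edges.
    expect_true(validate_cascades(surv))
    expect_true(all(ids %in% casc$tweet_id))
  }
  expect_true(found)
  # Tweets at or before t_int are exempt.
  surv <- prune_cascade(casc, 1, t_int = 2, seed = 9)
  expect_setequal(surv$tweet_id, c("t1", "t2", "t3"))
})

test_that("belief discount hits exactly the post-t_int exposures", {
  set.seed(7)
  ev <- tibble::tibble(
    user_id = sprintf("u%d", 1:20), article_id = "a1",
    exposure_time = c(runif(10, 0, 2), runif(10, 2.0001, 6)),
    via_tweet_id = "t1", score = 0,
    category = rep("Moderate", 20))
  p <- tibble::tibble(category = "Moderate", p = 0.8)
  out <- discount_belief(p, ev, belief_multiplier = 0.83, t_int = 2)
  # Event-by-event oracle.
  for (i in seq_len(20)) {
    expected <- if (ev$exposure_time[i] > 2) 0.8 * 0.83 else 0.8
    expect_equal(out$effective_p[i], expected)
  }
  # Identity multiplier.
  out1 <- discount_belief(p, ev, belief_multiplier = 1, t_int = 2)
  expect_equal(out1$effective_p, out1$p)
  # Global mode discounts everything.
  outg <- discount_belief(p, ev, belief_multiplier = 0.83, t_int = 2,
                          global = TRUE)
  expect_true(all(outg$effective_p == 0.8 * 0.83))
})

# One original tweet, k followers, all in one category with belief p = 1.
label_bundle <- function(k = 50) {
  followers <- sprintf("f%03d", seq_len(k))
  g <- social_graph(tibble::tibble(follower_id = followers,
                                   followee_id = "orig"))
  casc <- build_cascades(tweet_row("t1", "orig", 0), g)
  list(cascades = casc, graph = g,
       scores = scores_for(c(followers, "orig"), 0),
       belief = tibble::tibble(article_id = "a1", category = "Moderate",
                               p = 1))
}

test_that("type none gives exactly zero reduction under paired seeds", {
  b <- label_bundle()
  res <- run_intervention_experiment(b, types = "none", delays = c(0, 2),
                                     replicates = 3, seed = 5)
  expect_true(all(res$pct_reduction == 0))
  expect_true(all(res$receptive == res$baseline_receptive))
})

test_that("labeling with no retweets reduces r by exactly 17%", {
  b <- label_bundle()
  res <- run_intervention_experiment(b, types = "fact_check_label",
                                     delays = 0, replicates = 3, seed = 5)
  expect_equal(res$pct_reduction, rep(17, 3), tolerance = 1e-12)
  # Exposure counts are unchanged: only the belief discount acts.
  expect_equal(res$exposed, res$baseline_exposed)
})

test_that("friction removes ~75% of first-generation retweets", {
  k <- 10000
  rts <- tibble::tibble(
    tweet_id = sprintf("r%05d", seq_len(k)),
    user_id = sprintf("ru%05d", seq_len(k)),
    article_id = "a1",
    time = seq(0.001, 10, length.out = k),
    kind = "retweet", root_tweet_id = "t1",
    parent_tweet_id = "t1", rule = "orphan-attach")
  casc <- dplyr::bind_rows(
    dplyr::mutate(tweet_row("t1", "orig", 0), parent_tweet_id = NA_character_,
                  rule = NA_character_),
    rts)
  removal_rate <- function(type, seeds) {
    cfg <- intervention_config(type, t_int = 0)
    mean(vapply(seeds, function(s) {
      surv <- prune_cascade(casc, cfg$retweet_removal_prob, cfg$t_int,
                            seed = s)
      1 - (nrow(surv) - 1) / k
    }, numeric(1)))
  }
  expect_lt(abs(removal_rate("sharing_friction", 1:5) - 0.75), 0.01)
  # Labeling removal rate is 25% of eligible retweets.
  expect_lt(abs(removal_rate("fact_check_label", 1:5) - 0.25), 0.01)
})

test_that("visibility reduction removes the configured share of events", {
  b <- label_bundle(k = 10000)
  for (type in c("visibility_light", "visibility_heavy")) {
    cfg <- intervention_config(type, t_int = 0)
    ev <- compute_exposures(
      b$cascades, b$graph, b$scores,
      visibility_filter = list(prob = cfg$visibility_removal_prob,
                               t_int = 0),
      seed = 8)
    removed <- 1 - nrow(ev) / 10000
    expect_lt(abs(removed - cfg$visibility_removal_prob), 0.012)
  }
})

test_that("visibility with prob v on single-sharer articles scales exposure by 1 - v", {
  b <- label_bundle(k = 5000)
  res <- run_intervention_experiment(b, types = "visibility_light",
                                     delays = 0, replicates = 10, seed = 21)
  expect_equal(mean(res$exposed / res$baseline_exposed), 0.75,
               tolerance = 0.02)
})

test_that("mean receptive exposure is monotone in aggressiveness and delay", {
  # A cascade whose sharing spans the whole delay grid.
  set.seed(99)
  cfg <- synthetic_config(n_users = 500, n_articles = 1, n_seed_sharers = 2,
                          retweet_prob = 0.4, degree_exponent = 2.0,
                          wait_rate = 0.25, max_generations = 12, seed = 12)
  net <- generate_social_graph(cfg)
  ci <- generate_cascades(net, cfg)
  casc <- build_cascades(ci$tweets, net$graph)
  expect_gt(max(casc$time), 8)  # sharing continues past the largest delay
  scores <- net$truth[, c("user_id", "score")]
  bundle <- list(cascades = casc, graph = net$graph, scores = scores,
                 belief = flat_belief(0.5, article_id = ci$articles$article_id))

  # Aggressiveness: higher removal probability cannot increase receptive r.
  means <- vapply(c(0.25, 0.5, 0.9), function(pr) {
    res <- run_intervention_experiment(bundle, types = "sharing_friction",
                                       delays = 0, replicates = 50, seed = 3,
                                       retweet_removal_prob = pr)
    mean(res$receptive)
  }, numeric(1))
  expect_true(all(diff(means) < 0))

  # Delay: later deployment cannot increase the mean reduction.
  res <- run_intervention_experiment(bundle, types = "visibility_heavy",
                                     delays = c(0, 2, 6, 12),
                                     replicates = 50, seed = 4)
  agg <- summary(res)
  agg <- agg[order(agg$t_int), ]
  expect_true(all(diff(agg$mean_pct_reduction) <= 1e-9))
})
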