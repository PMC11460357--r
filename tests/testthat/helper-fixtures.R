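# Shared fixture builders. Everything is generated in code; no files.

# Graph from a list of "follower -> followee" strings, e.g. "b->a".
graph_from_spec <- function(spec) {
  parts <- strsplit(spec, "->", fixed = TRUE)
  social_graph(tibble::tibble(
    follower_id = vapply(parts, `[`, character(1), 1),
    followee_id = vapply(parts, `[`, character(1), 2)
  ))
}

tweet_row <- function(tweet_id, user_id, time, kind = "original",
                      root_tweet_id = NA_character_, article_id = "a1") {
  tibble::tibble(tweet_id = tweet_id, user_id = user_id,
                 article_id = article_id, time = time, kind = kind,
                 root_tweet_id = root_tweet_id)
}

# Random cascade scenario on a random directed graph: one original tweet and
# n_rt retweets of it at distinct times. Used against the brute-force oracle.
random_cascade_scenario <- function(n_users, n_rt, p_edge = 0.1,
                                    quote_frac = 0.2) {
  users <- sprintf("u%03d", seq_len(n_users))
  pairs <- expand.grid(follower_id = users, followee_id = users,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$follower_id != pairs$followee_id, ]
  edges <- pairs[runif(nrow(pairs)) < p_edge, ]
  graph <- social_graph(tibble::as_tibble(edges))
  tweeters <- sample(users, n_rt + 1)
  times <- c(0, sort(sample(seq(0.5, 50, by = 0.5), n_rt)))
  kinds <- c("original",
             ifelse(runif(n_rt) < quote_frac, "quote", "retweet"))
  tweets <- tibble::tibble(
    tweet_id = sprintf("t%03d", seq_len(n_rt + 1)),
    user_id = tweeters,
    article_id = "a1",
    time = times,
    kind = kinds,
    root_tweet_id = c(NA_character_, rep("t001", n_rt))
  )
  list(tweets = tweets, graph = graph)
}

# Independent brute-force implementation of the three parent-inference rules,
# written directly from their definition (no shared code with the package).
brute_force_parents <- function(tweets, graph) {
  out <- list()
  root <- tweets[tweets$kind == "original", ]
  for (i in seq_len(nrow(tweets))) {
    rt <- tweets[i, ]
    if (rt$kind == "original") next
    fr <- friends(graph, rt$user_id)
    if (root$user_id %in% fr) {
      out[[rt$tweet_id]] <- list(parent = root$tweet_id,
                                 rule = "direct-follow")
      next
    }
    cand_idx <- which(tweets$kind != "original" &
                        tweets$time < rt$time &
                        tweets$user_id %in% fr)
    if (length(cand_idx) > 0) {
      cand <- tweets[cand_idx, ]
      best <- cand[cand$time == max(cand$time), ]
      best <- best[order(best$tweet_id), ][1, ]
      out[[rt$tweet_id]] <- list(parent = best$tweet_id,
                                 rule = "friend-retweet")
    } else {
      out[[rt$tweet_id]] <- list(parent = root$tweet_id,
                                 rule = "orphan-attach")
    }
  }
  out
}

# A small belief table covering all 7 categories at a flat rate.
flat_belief <- function(p = 0.5, article_id = "a1") {
  tibble::tibble(article_id = article_id,
                 category = ideology_categories(), p = p)
}

# Score table assigning `score` to every user id given.
scores_for <- function(user_ids, score = 0) {
  tibble::tibble(user_id = user_ids, score = score)
}
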