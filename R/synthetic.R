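# Seed-controlled synthetic data with the statistical structure the method
# assumes: a directed follow graph that is heavy-tailed in follower count and
# ideologically homophilous, independent-cascade article sharing with
# exponential waiting times, partially observed ideology scores, and survey
# panels whose belief rates track ideological congruence with the article.

#' Synthetic-data configuration
#'
#' @param n_users Number of users.
#' @param ideology_means,ideology_sds,ideology_weights Mixture-of-normals
#'   ideology distribution (defaults: a moderate bulk plus left and right
#'   shoulders, weights summing to 1).
#' @param homophily Homophily strength (>= 0): follow probability decays with
#'   ideological distance through a logistic kernel `2 * plogis(-homophily *
#'   distance)`; 0 means distance-independent following.
#' @param degree_exponent Power-law exponent of the follower-count
#'   distribution (default 2.5).
#' @param degree_cap Maximum follower count (default `n_users - 1`).
#' @param observability Fraction of users whose true score is emitted as
#'   "known" (default 0.5).
#' @param n_articles Number of articles.
#' @param n_seed_sharers Original sharers per article (default 3).
#' @param retweet_prob Per-exposed-follower retweet probability (default
#'   0.05).
#' @param wait_rate Rate of the exponential retweet waiting time, per hour
#'   (default 0.5, i.e. mean 2 h).
#' @param quote_prob Fraction of reshares emitted as quote tweets (default
#'   0.1).
#' @param max_generations Cap on cascade depth (default 8).
#' @param n_respondents Survey respondents per article (default 90, balanced
#'   across the 7 ideology categories).
#' @param belief_intercept,belief_alignment,belief_quality Logistic
#'   coefficients of the survey belief model: belief probability is
#'   `plogis(intercept + alignment * congruence + quality * article_quality)`
#'   where congruence is the product of the category midpoint (rescaled to
#'   `[-1, 1]`) and the article slant.
#' @param seed Integer seed controlling all generation.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_users = 1000,
                             ideology_means = c(-1.2, 0, 1.2),
                             ideology_sds = c(0.8, 0.8, 0.8),
                             ideology_weights = c(0.3, 0.4, 0.3),
                             homophily = 1.5,
                             degree_exponent = 2.5,
                             degree_cap = NULL,
                             observability = 0.5,
                             n_articles = 1,
                             n_seed_sharers = 3,
                             retweet_prob = 0.05,
                             wait_rate = 0.5,
                             quote_prob = 0.1,
                             max_generations = 8,
                             n_respondents = 90,
                             belief_intercept = -0.3,
                             belief_alignment = 2.5,
                             belief_quality = 1.0,
                             seed = 1L) {
  if (abs(sum(ideology_weights) - 1) > 1e-8) {
    abort("`ideology_weights` must sum to 1.",
          class = "receptr_validation_error")
  }
  if (homophily < 0) abort("`homophily` must be >= 0.",
                           class = "receptr_validation_error")
  assert_prob(observability, "observability")
  assert_prob(retweet_prob, "retweet_prob")
  assert_prob(quote_prob, "quote_prob")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a homophilous follow graph with ground-truth ideology
#'
#' Draws each user's true ideology from the configured normal mixture and a
#' follower count from a capped discrete power law, then selects each user's
#' followers with probability proportional to a logistic kernel of ideological
#' distance. Only the configured observability fraction of scores is emitted
#' as known.
#'
#' @param config A [synthetic_config()].
#' @param seed Seed override (defaults to `config$seed`).
#' @return List with `graph` ([social_graph()]), `known_scores` (tibble
#'   `user_id`, `score`), and `truth` (tibble `user_id`, `score`, `observed`).
#' @export
generate_social_graph <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_users
  cap <- config$degree_cap %||% (n - 1)
  cap <- min(cap, n - 1)
  with_seed_or_current(seed, {
    comp <- sample.int(length(config$ideology_weights), n, replace = TRUE,
                       prob = config$ideology_weights)
    score <- rnorm(n, config$ideology_means[comp], config$ideology_sds[comp])
    user_id <- sprintf("u%05d", seq_len(n))
    deg_support <- seq_len(cap)
    deg_prob <- deg_support^(-config$degree_exponent)
    n_followers <- sample(deg_support, n, replace = TRUE, prob = deg_prob)
    # Above ~10k users the follower pool per account is subsampled before the
    # weighted draw; the homophily kernel still governs selection within the
    # pool, keeping the edge-level distance distribution intact at scale.
    pool_cap <- if (n > 10000) 5000L else n - 1L
    edges <- purrr::map(seq_len(n), function(i) {
      k <- min(n_followers[i], pool_cap)
      if (k == 0) return(NULL)
      others <- if (pool_cap < n - 1L) {
        cand <- sample.int(n, min(n, pool_cap + 1L))
        setdiff(cand, i)[seq_len(min(pool_cap, n - 1L))]
      } else {
        setdiff(seq_len(n), i)
      }
      w <- 2 * stats::plogis(-config$homophily * abs(score[others] - score[i]))
      picked <- others[sample.int(length(others), min(k, length(others)),
                                  prob = w)]
      tibble(follower_id = user_id[picked], followee_id = user_id[i])
    })
    edges <- bind_rows(edges)
    observed <- runif(n) < config$observability
    truth <- tibble(user_id = user_id, score = score, observed = observed)
    list(graph = social_graph(edges),
         known_scores = truth %>% filter(.data$observed) %>%
           select("user_id", "score"),
         truth = truth)
  })
}

#' Generate sharing cascades over a follow graph
#'
#' Independent-cascade spread per article: seed sharers (chosen with
#' probability proportional to follower count, emulating the large-account
#' head start of viral articles) tweet at staggered early times; every exposed
#' follower of a sharer retweets with the configured probability after an
#' exponential waiting time, at most once per article. Tweets carry the
#' platform convention that retweets reference the cascade's *original* tweet;
#' the true parent links are returned as ground truth.
#'
#' @param net A [generate_social_graph()] result.
#' @param config A [synthetic_config()].
#' @param seed Seed override.
#' @return List with `tweets` (input format for [build_cascades()]),
#'   `articles` (tibble `article_id`, `veracity`, `slant`, `quality`), and
#'   `true_parents` (tibble `tweet_id`, `true_parent_tweet_id`).
#' @export
generate_cascades <- function(net, config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  graph <- net$graph
  truth <- net$truth
  with_seed_or_current(derive_seed(seed, 101L), {
    fcount <- lengths(graph$followers_idx)[truth$user_id]
    fcount[is.na(fcount)] <- 0
    articles <- tibble(
      article_id = sprintf("a%03d", seq_len(config$n_articles)),
      veracity = sample(c("true", "false_misleading"), config$n_articles,
                        replace = TRUE, prob = c(0.6, 0.4)),
      slant = runif(config$n_articles, -1, 1),
      quality = runif(config$n_articles, 0, 1)
    )
    tweets_all <- list()
    parents_all <- list()
    counter <- 0L
    for (ai in seq_len(config$n_articles)) {
      aid <- articles$article_id[ai]
      n_seed <- min(config$n_seed_sharers, nrow(truth))
      # Viral articles are initially shared by large accounts: weight seed
      # selection by squared follower count so the head of the degree
      # distribution dominates even at toy scale.
      seeds <- sample(truth$user_id, n_seed, prob = (fcount + 1)^2)
      seed_times <- c(0, sort(rexp(n_seed - 1, rate = 1)))
      tweeted <- character(0)
      frontier <- list()
      rows <- list()
      parent_rows <- list()
      for (s in seq_along(seeds)) {
        counter <- counter + 1L
        tid <- sprintf("t%06d", counter)
        rows[[length(rows) + 1]] <- tibble(
          tweet_id = tid, user_id = seeds[s], article_id = aid,
          time = seed_times[s], kind = "original",
          root_tweet_id = NA_character_)
        parent_rows[[length(parent_rows) + 1]] <-
          tibble(tweet_id = tid, true_parent_tweet_id = NA_character_)
        frontier[[length(frontier) + 1]] <-
          list(tweet_id = tid, user_id = seeds[s], time = seed_times[s],
               root = tid, gen = 0L)
        tweeted <- c(tweeted, seeds[s])
      }
      while (length(frontier) > 0) {
        node <- frontier[[1]]
        frontier <- frontier[-1]
        if (node$gen >= config$max_generations) next
        fols <- setdiff(followers(graph, node$user_id), tweeted)
        if (length(fols) == 0) next
        shares <- fols[runif(length(fols)) < config$retweet_prob]
        for (u in shares) {
          if (u %in% tweeted) next
          counter <- counter + 1L
          tid <- sprintf("t%06d", counter)
          t_new <- node$time + rexp(1, rate = config$wait_rate) + 1e-6
          kind <- if (runif(1) < config$quote_prob) "quote" else "retweet"
          rows[[length(rows) + 1]] <- tibble(
            tweet_id = tid, user_id = u, article_id = aid, time = t_new,
            kind = kind, root_tweet_id = node$root)
          parent_rows[[length(parent_rows) + 1]] <-
            tibble(tweet_id = tid, true_parent_tweet_id = node$tweet_id)
          frontier[[length(frontier) + 1]] <-
            list(tweet_id = tid, user_id = u, time = t_new, root = node$root,
                 gen = node$gen + 1L)
          tweeted <- c(tweeted, u)
        }
      }
      tweets_all[[ai]] <- bind_rows(rows)
      parents_all[[ai]] <- bind_rows(parent_rows)
    }
    tweets <- bind_rows(tweets_all)
    # Times are hours since the article's first share by construction.
    list(tweets = tweets, articles = articles,
         true_parents = bind_rows(parents_all))
  })
}

# Midpoints of the 7 categories rescaled to [-1, 1] for the belief model.
category_alignment <- function(category) {
  mid <- c("Very Liberal" = -3, "Liberal" = -2, "Somewhat Liberal" = -1,
           "Moderate" = 0, "Somewhat Conservative" = 1, "Conservative" = 2,
           "Very Conservative" = 3) / 3
  unname(mid[as.character(category)])
}

# True belief probability for a category x article under the logistic model.
true_belief_prob <- function(category, slant, quality, config) {
  stats::plogis(config$belief_intercept +
                  config$belief_alignment * category_alignment(category) *
                  slant +
                  config$belief_quality * quality)
}

#' Generate survey responses
#'
#' Per article, draws a balanced panel across the seven ideology categories
#' and samples each respondent's rating from the article's true belief
#' probability for that category (logistic in congruence between category and
#' article slant, plus article quality). Non-believers split between
#' "false_misleading" and "could_not_determine".
#'
#' @param articles Tibble with `article_id`, `slant`, `quality` (from
#'   [generate_cascades()]).
#' @param config A [synthetic_config()].
#' @param seed Seed override.
#' @return List with `responses` (input format for [compute_belief_table()])
#'   and `truth` (tibble `article_id`, `category`, `p_true`).
#' @export
generate_survey <- function(articles, config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  cats <- ideology_categories()
  with_seed_or_current(derive_seed(seed, 202L), {
    resp_all <- list()
    truth_all <- list()
    for (ai in seq_len(nrow(articles))) {
      aid <- articles$article_id[ai]
      n <- config$n_respondents
      base <- rep(cats, length.out = n)   # balanced: counts within 1 of n/7
      p_cat <- true_belief_prob(cats, articles$slant[ai],
                                articles$quality[ai], config)
      names(p_cat) <- cats
      p_resp <- p_cat[base]
      believes <- runif(n) < p_resp
      other <- sample(c("false_misleading", "could_not_determine"), n,
                      replace = TRUE, prob = c(0.7, 0.3))
      resp_all[[ai]] <- tibble(
        respondent_id = sprintf("%s_r%04d", aid, seq_len(n)),
        article_id = aid,
        rating = if_else(believes, "true", other),
        category = base)
      truth_all[[ai]] <- tibble(article_id = aid, category = cats,
                                p_true = unname(p_cat))
    }
    list(responses = bind_rows(resp_all), truth = bind_rows(truth_all))
  })
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates a follow graph, cascades, partial scores, survey responses, and
#' article metadata at one of three scales and writes them in the package's
#' input formats, together with a ground-truth JSON.
#'
#' @param scale One of `"tiny"` (~200 users, 1 article), `"small"` (~5,000
#'   users, 3 articles), `"medium"` (~50,000 users, 10 articles).
#' @param seed Integer seed; the same seed yields a byte-identical bundle.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of file paths written.
#' @export
make_demo_dataset <- function(scale = c("tiny", "small", "medium"), seed = 1L,
                              dir = tempfile("receptr_demo_")) {
  scale <- match.arg(scale)
  config <- switch(scale,
    tiny = synthetic_config(n_users = 200, n_articles = 1,
                            n_seed_sharers = 2, retweet_prob = 0.15,
                            degree_exponent = 2.2, degree_cap = 60,
                            seed = seed),
    small = synthetic_config(n_users = 5000, n_articles = 3,
                             n_seed_sharers = 3, retweet_prob = 0.08,
                             degree_exponent = 2.2, degree_cap = 800,
                             seed = seed),
    medium = synthetic_config(n_users = 50000, n_articles = 10,
                              n_seed_sharers = 4, retweet_prob = 0.05,
                              degree_exponent = 2.3, degree_cap = 5000,
                              seed = seed))
  net <- generate_social_graph(config)
  casc <- generate_cascades(net, config)
  surv <- generate_survey(casc$articles, config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    tweets = file.path(dir, "tweets.csv"),
    edges = file.path(dir, "follow_edges.csv"),
    scores = file.path(dir, "ideology_scores.csv"),
    survey = file.path(dir, "survey.csv"),
    articles = file.path(dir, "articles.csv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  readr::write_csv(casc$tweets, paths$tweets)
  readr::write_csv(net$graph$edges, paths$edges)
  readr::write_csv(net$known_scores, paths$scores)
  readr::write_csv(surv$responses, paths$survey)
  readr::write_csv(casc$articles, paths$articles)
  jsonlite::write_json(
    list(scale = scale, seed = seed,
         scores = net$truth,
         true_parents = casc$true_parents,
         belief = surv$truth),
    paths$ground_truth, dataframe = "columns", digits = NA)
  invisible(paths)
}
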