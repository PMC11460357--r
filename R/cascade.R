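# Time-inferred retweet-cascade reconstruction. Platform data attach every
# retweet to the *original* tweet even when it was seen via an intermediate
# sharer, so the true diffusion path is inferred from timing and the
# friend/follower network:
#   1. the retweeter follows the original tweeter  -> direct retweet;
#   2. otherwise, the retweet flowed from the friend who most recently shared
#      the same root tweet strictly before it;
#   3. otherwise it is attached to the original tweet (content reached the
#      user outside their follow graph).

TWEET_KINDS <- c("original", "retweet", "quote")

validate_tweets <- function(tweets) {
  assert_columns(tweets, c("tweet_id", "user_id", "article_id", "time", "kind"),
                 "tweets")
  if (!"root_tweet_id" %in% names(tweets)) tweets$root_tweet_id <- NA_character_
  tweets <- mutate(tweets,
                   tweet_id = as.character(.data$tweet_id),
                   user_id = as.character(.data$user_id),
                   article_id = as.character(.data$article_id),
                   root_tweet_id = as.character(.data$root_tweet_id))
  bad_kind <- !tweets$kind %in% TWEET_KINDS
  if (any(bad_kind)) {
    abort(sprintf("Unknown tweet kind(s): %s",
                  paste(unique(tweets$kind[bad_kind]), collapse = ", ")),
          class = "receptr_schema_error")
  }
  if (any(tweets$time < 0 | !is.finite(tweets$time))) {
    abort("Tweet times must be finite and >= 0 (hours since first share).",
          class = "receptr_validation_error")
  }
  need_root <- tweets$kind != "original"
  if (any(need_root & is.na(tweets$root_tweet_id))) {
    abort("Retweets and quotes must carry `root_tweet_id`.",
          class = "receptr_schema_error")
  }
  if (any(!need_root & !is.na(tweets$root_tweet_id))) {
    abort("Original tweets must not carry `root_tweet_id`.",
          class = "receptr_schema_error")
  }
  if (anyDuplicated(tweets$tweet_id) > 0) {
    abort("`tweet_id` must be unique.", class = "receptr_schema_error")
  }
  tweets
}

#' Infer the parent of a single retweet
#'
#' Applies the three time-inferred diffusion rules to one retweet or quote
#' tweet: direct follow of the original tweeter wins; otherwise the friend who
#' most recently shared the same root strictly before the retweet; otherwise
#' the retweet is attached to the original tweet. Equal candidate times are
#' broken toward the lowest `tweet_id` so reconstruction is deterministic.
#'
#' @param rt One-row data frame (or list) for the retweet: `tweet_id`,
#'   `user_id`, `time`.
#' @param root One-row data frame for the original tweet being retweeted.
#' @param prior_shares Data frame of earlier shares of the same root
#'   (`tweet_id`, `user_id`, `time`); rows at or after `rt$time` are ignored.
#' @param graph A [social_graph()].
#' @return List with `parent_tweet_id` and `rule` (one of "direct-follow",
#'   "friend-retweet", "orphan-attach").
#' @export
infer_retweet_parent <- function(rt, root, prior_shares, graph) {
  if (is.null(root) || nrow(as.data.frame(root)) == 0) {
    abort("Root tweet is missing.", class = "receptr_structural_error")
  }
  if (rt$time <= root$time) {
    abort(sprintf("Retweet %s is not later than its root (%.4g <= %.4g h).",
                  rt$tweet_id, rt$time, root$time),
          class = "receptr_temporal_error")
  }
  fr <- friends(graph, rt$user_id)
  if (as.character(root$user_id) %in% fr) {
    return(list(parent_tweet_id = as.character(root$tweet_id),
                rule = "direct-follow"))
  }
  if (!is.null(prior_shares) && nrow(prior_shares) > 0) {
    cand <- prior_shares[prior_shares$time < rt$time &
                           as.character(prior_shares$user_id) %in% fr, ,
                         drop = FALSE]
    if (nrow(cand) > 0) {
      cand <- cand[order(-cand$time, as.character(cand$tweet_id)), ,
                   drop = FALSE]
      return(list(parent_tweet_id = as.character(cand$tweet_id[1]),
                  rule = "friend-retweet"))
    }
  }
  list(parent_tweet_id = as.character(root$tweet_id), rule = "orphan-attach")
}

#' Reconstruct retweet cascades for every article
#'
#' Builds the time-inferred diffusion forest per article: every retweet/quote
#' is assigned exactly one parent by [infer_retweet_parent()]. Retweets whose
#' root tweet is absent from the table are dropped with a warning; other
#' articles are unaffected. Output ordering and parent assignment are
#' invariant to input row order.
#'
#' @param tweets Data frame of tweets: `tweet_id`, `user_id`, `article_id`,
#'   `time` (hours since the article's first share), `kind` (original /
#'   retweet / quote), `root_tweet_id` (non-originals only).
#' @param graph A [social_graph()].
#' @return Tibble of class `cascade_set`: the tweet columns plus
#'   `parent_tweet_id` and `rule` (NA for original tweets), sorted by article,
#'   time, and tweet id.
#' @export
build_cascades <- function(tweets, graph) {
  tweets <- validate_tweets(as_tibble(tweets))
  tweets <- arrange(tweets, .data$article_id, .data$time, .data$tweet_id)
  known_ids <- tweets$tweet_id
  root_kind <- setNames(tweets$kind, tweets$tweet_id)

  nonorig <- tweets$kind != "original"
  dangling <- nonorig & !(tweets$root_tweet_id %in% known_ids)
  bad_root <- nonorig & !dangling &
    root_kind[tweets$root_tweet_id] != "original"
  if (any(dangling | bad_root)) {
    warn(sprintf(
      "Dropping %d retweet(s)/quote(s) with missing or non-original root tweets.",
      sum(dangling | bad_root)))
    tweets <- tweets[!(dangling | bad_root), , drop = FALSE]
  }

  tweets$parent_tweet_id <- NA_character_
  tweets$rule <- NA_character_

  for (aid in unique(tweets$article_id)) {
    a_rows <- which(tweets$article_id == aid)
    at <- tweets[a_rows, ]
    for (rid in unique(at$root_tweet_id[at$kind != "original"])) {
      root_i <- which(at$tweet_id == rid)
      root <- at[root_i, ]
      share_rows <- which(at$root_tweet_id %in% rid)
      shares <- at[share_rows, ]        # time-sorted by construction
      for (k in seq_len(nrow(shares))) {
        rt <- shares[k, ]
        prior <- shares[seq_len(k - 1), , drop = FALSE]
        res <- infer_retweet_parent(rt, root, prior, graph)
        idx <- a_rows[share_rows[k]]
        tweets$parent_tweet_id[idx] <- res$parent_tweet_id
        tweets$rule[idx] <- res$rule
      }
    }
  }
  class(tweets) <- c("cascade_set", class(tweets))
  tweets
}

#' Check cascade forest invariants
#'
#' Verifies that a reconstructed (or pruned) cascade set is a valid forest:
#' every non-original tweet has exactly one parent that exists in the set,
#' friend-retweet parents precede their children in time, and there are no
#' cycles.
#'
#' @param cascades A [build_cascades()] result.
#' @return Invisibly `TRUE`; aborts with a descriptive error otherwise.
#' @export
validate_cascades <- function(cascades) {
  co <- cascades
  nonorig <- co$kind != "original"
  if (any(is.na(co$parent_tweet_id[nonorig]))) {
    abort("Non-original tweet without a parent.",
          class = "receptr_structural_error")
  }
  if (any(!is.na(co$parent_tweet_id[!nonorig]))) {
    abort("Original tweet with a parent.", class = "receptr_structural_error")
  }
  if (any(!co$parent_tweet_id[nonorig] %in% co$tweet_id)) {
    abort("Parent tweet missing from cascade.",
          class = "receptr_structural_error")
  }
  parent_time <- setNames(co$time, co$tweet_id)[co$parent_tweet_id[nonorig]]
  fr_rule <- co$rule[nonorig] == "friend-retweet"
  if (any(parent_time[fr_rule] >= co$time[nonorig][fr_rule])) {
    abort("friend-retweet parent not strictly earlier than child.",
          class = "receptr_temporal_error")
  }
  # Acyclic: walk up from every node; depth bounded by cascade size.
  parent_map <- setNames(co$parent_tweet_id, co$tweet_id)
  for (id in co$tweet_id) {
    seen <- character(0)
    cur <- id
    while (!is.na(parent_map[cur])) {
      if (cur %in% seen) abort("Cycle detected in cascade.",
                               class = "receptr_structural_error")
      seen <- c(seen, cur)
      cur <- parent_map[[cur]]
    }
  }
  invisible(TRUE)
}
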