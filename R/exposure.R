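# Follower exposure under the viewing-delay model. Every follower of a sharer
# is assumed to (eventually) see the share: each (follower, tweet) pair gets a
# candidate exposure at tweet time plus a random delay from a truncated normal
# (default mu = 1 h, sigma = 2 h, lower bound 0). Exposure is a one-time event
# per (user, article): after optional visibility filtering, only the earliest
# candidate per user per article is kept.

#' Viewing-delay model
#'
#' Truncated-normal delay (in hours) between a tweet and a follower seeing it.
#'
#' @param mu Mean parameter of the untruncated normal, hours (default 1).
#' @param sigma SD parameter, hours (default 2, must be > 0).
#' @param lower Lower truncation bound (fixed at 0 hours).
#' @return A `delay_model` list.
#' @export
delay_model <- function(mu = 1, sigma = 2, lower = 0) {
  if (!is.numeric(sigma) || sigma <= 0) {
    abort("`sigma` must be > 0.", class = "receptr_validation_error")
  }
  if (!identical(lower, 0) && lower != 0) {
    abort("The delay model is truncated at 0 hours.",
          class = "receptr_validation_error")
  }
  structure(list(mu = mu, sigma = sigma, lower = 0), class = "delay_model")
}

#' Sample viewing delays
#'
#' Inverse-CDF draws from the truncated normal delay model, so results are
#' reproducible under a seed regardless of platform rejection behaviour.
#'
#' @param n Number of delays (>= 0).
#' @param model A [delay_model()].
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` non-negative delays in hours.
#' @export
sample_exposure_delays <- function(n, model = delay_model(), seed = NULL) {
  stopifnot(inherits(model, "delay_model"))
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0) {
    abort("`n` must be a single count >= 0.",
          class = "receptr_validation_error")
  }
  with_seed_or_current(seed,
                       rtruncnorm_inv(as.integer(n), model$mu, model$sigma,
                                      lower = model$lower))
}

#' Compute per-user exposure events from surviving tweets
#'
#' One candidate event is created per (follower, tweet) pair with
#' `exposure_time = tweet time + delay`. If a visibility filter is supplied,
#' candidate events later than `t_int` are independently dropped with the
#' given probability *before* deduplication, so a user can miss their first
#' exposure chance but still be exposed through a later share. Finally only
#' the earliest event per (user, article) is kept.
#'
#' @param cascades A [build_cascades()] result (possibly pruned) — the
#'   surviving tweets.
#' @param graph A [social_graph()].
#' @param scores Data frame of per-user ideology (`user_id`, `score`), which
#'   must cover every follower of a surviving sharer (see
#'   [assign_follower_scores()]).
#' @param model A [delay_model()].
#' @param visibility_filter Optional `list(prob = , t_int = )` removal filter.
#' @param include_sharers Count sharers themselves as exposed at delay 0?
#'   Default `FALSE`: exposure is follower-based.
#' @param seed Optional integer seed.
#' @return Tibble of deduplicated exposure events: `user_id`, `article_id`,
#'   `exposure_time`, `via_tweet_id`, `score`, `category`.
#' @export
compute_exposures <- function(cascades, graph, scores, model = delay_model(),
                              visibility_filter = NULL,
                              include_sharers = FALSE, seed = NULL) {
  stopifnot(inherits(graph, "social_graph"))
  assert_columns(scores, c("user_id", "score"), "scores")
  assert_columns(cascades, c("tweet_id", "user_id", "article_id", "time"),
                 "cascades")
  if (!is.null(visibility_filter)) {
    assert_prob(visibility_filter$prob, "visibility_filter$prob")
    if (is.null(visibility_filter$t_int) || visibility_filter$t_int < 0) {
      abort("`visibility_filter$t_int` must be >= 0.",
            class = "receptr_validation_error")
    }
  }
  tw <- as_tibble(cascades)[, c("tweet_id", "user_id", "article_id", "time")]
  follower_sets <- lapply(tw$user_id, function(u) followers(graph, u))
  n_missing <- sum(!tw$user_id %in% names(graph$followers_idx))
  if (n_missing > 0) {
    inform(sprintf(
      "compute_exposures: %d sharer(s) have no follower list; treated as empty.",
      n_missing))
  }
  n_fol <- lengths(follower_sets)
  cand <- tibble(
    user_id = unlist(follower_sets, use.names = FALSE) %||% character(0),
    article_id = rep(tw$article_id, n_fol),
    via_tweet_id = rep(tw$tweet_id, n_fol),
    tweet_time = rep(tw$time, n_fol)
  )
  events <- with_seed_or_current(seed, {
    ev <- cand
    ev$exposure_time <- ev$tweet_time +
      rtruncnorm_inv(nrow(ev), model$mu, model$sigma, lower = model$lower)
    if (!is.null(visibility_filter) && visibility_filter$prob > 0) {
      eligible <- ev$exposure_time > visibility_filter$t_int
      drop <- eligible & (runif(nrow(ev)) < visibility_filter$prob)
      ev <- ev[!drop, , drop = FALSE]
    }
    ev
  })
  if (include_sharers) {
    sharer_ev <- tibble(user_id = tw$user_id, article_id = tw$article_id,
                        via_tweet_id = tw$tweet_id, tweet_time = tw$time,
                        exposure_time = tw$time)
    events <- bind_rows(events, sharer_ev)
  }
  events <- events %>%
    arrange(.data$article_id, .data$user_id, .data$exposure_time,
            .data$via_tweet_id) %>%
    distinct(.data$article_id, .data$user_id, .keep_all = TRUE)
  missing_scores <- setdiff(events$user_id, scores$user_id)
  if (length(missing_scores) > 0) {
    abort(sprintf("%d exposed user(s) have no ideology assignment.",
                  length(missing_scores)),
          class = "receptr_schema_error")
  }
  events %>%
    left_join(distinct(scores, .data$user_id, .keep_all = TRUE),
              by = "user_id") %>%
    mutate(category = bin_score(.data$score)) %>%
    select("user_id", "article_id", "exposure_time", "via_tweet_id",
           "score", "category") %>%
    arrange(.data$article_id, .data$exposure_time, .data$user_id)
}

#' Tabulate exposure counts by ideology category
#'
#' Produces x_ij — the number of unique exposed users per ideology category i
#' and article j — plus a cumulative exposure time series at the requested
#' resolution.
#'
#' @param events Deduplicated exposure events from [compute_exposures()].
#' @param bin_width Time-series bin width in hours (default 0.5).
#' @return An `exposure_table`: list with `counts` (article_id, category, n),
#'   `series` (article_id, time_bin, new_exposures, cumulative), the events,
#'   and the bin width.
#' @export
tabulate_exposures <- function(events, bin_width = 0.5) {
  assert_columns(events, c("user_id", "article_id", "exposure_time",
                           "category"), "events")
  if (anyDuplicated(events[, c("user_id", "article_id")]) > 0) {
    abort("Events must be deduplicated per (user, article).",
          class = "receptr_validation_error")
  }
  cats <- ideology_categories()
  counts <- events %>%
    mutate(category = factor(as.character(.data$category), levels = cats)) %>%
    count(.data$article_id, .data$category, .drop = FALSE, name = "n") %>%
    as_tibble()
  if (nrow(events) == 0) {
    counts <- tibble(article_id = character(0),
                     category = factor(character(0), levels = cats),
                     n = integer(0))
  }
  series <- events %>%
    mutate(time_bin = floor(.data$exposure_time / bin_width) * bin_width) %>%
    count(.data$article_id, .data$time_bin, name = "new_exposures") %>%
    arrange(.data$article_id, .data$time_bin) %>%
    group_by(.data$article_id) %>%
    mutate(cumulative = cumsum(.data$new_exposures)) %>%
    ungroup()
  structure(list(counts = counts, series = series, events = as_tibble(events),
                 bin_width = bin_width),
            class = "exposure_table")
}

#' @export
print.exposure_table <- function(x, ...) {
  cat(sprintf("<exposure_table> %d unique exposures across %d article(s)\n",
              nrow(x$events), length(unique(x$counts$article_id))))
  print(tidyr::pivot_wider(x$counts, names_from = "category",
                           values_from = "n"))
  invisible(x)
}

#' @rdname tabulate_exposures
#' @param x An `exposure_table`.
#' @param ... Unused.
#' @export
tidy.exposure_table <- function(x, ...) x$counts

#' @rdname tabulate_exposures
#' @export
glance.exposure_table <- function(x, ...) {
  x$counts %>%
    group_by(.data$article_id) %>%
    summarise(exposed = sum(.data$n), .groups = "drop")
}
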