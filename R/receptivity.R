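# Survey-based belief rates and the receptive-exposure estimator
# r_j = sum_i x_ij * p_ij: exposed-user counts per ideology category are
# weighted by the proportion of same-category survey respondents who rated
# the article "true". Only affirmative belief counts; respondents who could
# not determine veracity stay in the denominator.

SURVEY_RATINGS <- c("true", "false_misleading", "could_not_determine")

#' Compute survey belief rates p_ij
#'
#' p_ij is the proportion of respondents in ideology category i who rated
#' article j "true", out of all ratings in that cell (including
#' "could_not_determine": only affirmative belief counts toward receptivity).
#'
#' @param responses Data frame of survey responses: `respondent_id`,
#'   `article_id`, `rating` (one of "true", "false_misleading",
#'   "could_not_determine"), `category` (one of the 7 labels).
#' @param on_empty_cell What to do when an (article, category) cell has no
#'   respondents: `"error"` (default) or `"pool"` — fall back to the
#'   article-wide pooled rate with a loud message.
#' @return A `belief_table`: tibble with `article_id`, `category`, `p`, `n`
#'   (respondent count), `pooled` flag.
#' @examples
#' resp <- tibble::tibble(
#'   respondent_id = as.character(1:10), article_id = "a1",
#'   rating = c(rep("true", 7), rep("false_misleading", 2),
#'              "could_not_determine"),
#'   category = "Moderate")
#' compute_belief_table(resp)$p  # 0.7
#' @export
compute_belief_table <- function(responses, on_empty_cell = c("error", "pool")) {
  on_empty_cell <- match.arg(on_empty_cell)
  assert_columns(responses, c("respondent_id", "article_id", "rating",
                              "category"), "responses")
  bad <- !responses$rating %in% SURVEY_RATINGS
  if (any(bad)) {
    abort(sprintf("Unknown rating value(s): %s",
                  paste(unique(responses$rating[bad]), collapse = ", ")),
          class = "receptr_schema_error")
  }
  bad_cat <- !responses$category %in% ideology_categories()
  if (any(bad_cat)) {
    abort(sprintf("Unknown ideology category value(s): %s",
                  paste(unique(responses$category[bad_cat]), collapse = ", ")),
          class = "receptr_schema_error")
  }
  if (anyDuplicated(responses[, c("respondent_id", "article_id")]) > 0) {
    abort("Each respondent may rate an article only once.",
          class = "receptr_schema_error")
  }
  cats <- ideology_categories()
  tab <- responses %>%
    mutate(category = factor(.data$category, levels = cats)) %>%
    group_by(.data$article_id, .data$category, .drop = FALSE) %>%
    summarise(n = dplyr::n(), n_true = sum(.data$rating == "true"),
              .groups = "drop") %>%
    mutate(p = ifelse(.data$n > 0, .data$n_true / .data$n, NA_real_),
           pooled = FALSE)
  empty <- tab$n == 0
  if (any(empty)) {
    if (on_empty_cell == "error") {
      abort(sprintf(
        "%d (article, category) survey cell(s) have no respondents; set on_empty_cell = \"pool\" to fall back to article-wide rates.",
        sum(empty)), class = "receptr_empty_cell_error")
    }
    pooled <- responses %>%
      group_by(.data$article_id) %>%
      summarise(p_pool = mean(.data$rating == "true"), .groups = "drop")
    tab <- tab %>%
      left_join(pooled, by = "article_id") %>%
      mutate(pooled = .data$n == 0,
             p = if_else(.data$pooled, .data$p_pool, .data$p)) %>%
      select(-"p_pool")
    warn(sprintf(
      "compute_belief_table: %d empty cell(s) filled with article-wide pooled belief rates.",
      sum(empty)))
  }
  structure(
    tab %>% select("article_id", "category", "p", "n", "pooled"),
    class = c("belief_table", class(tab)))
}

# Coerce a loose belief spec (belief_table, or tibble with category/p and
# optional article_id) to the canonical long form.
as_belief_tbl <- function(p) {
  if (inherits(p, "belief_table")) return(as_tibble(p))
  p <- as_tibble(p)
  assert_columns(p, c("category", "p"), "belief table")
  if (!"article_id" %in% names(p)) p$article_id <- "article"
  if (!"n" %in% names(p)) p$n <- NA_integer_
  p
}

as_exposure_counts <- function(x) {
  if (inherits(x, "exposure_table")) return(x$counts)
  x <- as_tibble(x)
  assert_columns(x, c("category", "n"), "exposure counts")
  if (!"article_id" %in% names(x)) x$article_id <- "article"
  x
}

#' Estimate exposed-and-receptive users
#'
#' Computes r_j = sum_i x_ij * p_ij per article from an exposure table and a
#' belief table, plus — when per-event timing is available — the receptive
#' time series obtained by weighting each exposure event by its category
#' belief rate.
#'
#' @param x An [tabulate_exposures()] result, or a tibble with columns
#'   `category`, `n` (and optionally `article_id`).
#' @param p A [compute_belief_table()] result, or a tibble with columns
#'   `category`, `p` (and optionally `article_id`).
#' @param belief_multiplier Global multiplier in `[0, 1]` applied to every
#'   belief rate (used by the fact-check-label intervention), or a per-event
#'   multiplier vector when `x` carries events.
#' @param bin_width Time-series bin width in hours (default 0.5).
#' @return A `receptivity_estimate` with per-article totals `r`, per-category
#'   `contributions` (x_ij * p_ij), and, if available, the cumulative
#'   receptive time `series`.
#' @export
estimate_receptivity <- function(x, p, belief_multiplier = 1,
                                 bin_width = 0.5) {
  counts <- as_exposure_counts(x)
  beliefs <- as_belief_tbl(p)
  counts$category <- as.character(counts$category)
  beliefs$category <- as.character(beliefs$category)
  per_article_p <- length(unique(beliefs$article_id)) > 1 ||
    all(counts$article_id %in% beliefs$article_id)
  join_by <- if (per_article_p) c("article_id", "category") else "category"
  if (!per_article_p) beliefs$article_id <- NULL
  contributions <- counts %>%
    filter(.data$n > 0) %>%
    left_join(select(beliefs, -dplyr::any_of("n")), by = join_by)
  if (any(is.na(contributions$p))) {
    miss <- contributions %>% filter(is.na(.data$p))
    abort(sprintf(
      "No belief rate for %d exposed (article, category) cell(s), e.g. %s / %s.",
      nrow(miss), miss$article_id[1], miss$category[1]),
      class = "receptr_schema_error")
  }
  if (length(belief_multiplier) != 1) {
    abort("`belief_multiplier` must be a single factor; per-event discounting is handled by `discount_belief()`.",
          class = "receptr_validation_error")
  }
  assert_prob(belief_multiplier, "belief_multiplier")
  contributions <- contributions %>%
    mutate(contribution = .data$n * .data$p * belief_multiplier) %>%
    select("article_id", "category", "n", "p", "contribution")
  totals <- contributions %>%
    group_by(.data$article_id) %>%
    summarise(exposed = sum(.data$n), r = sum(.data$contribution),
              .groups = "drop")

  series <- NULL
  weighted_events <- NULL
  events <- if (inherits(x, "exposure_table")) x$events else NULL
  if (!is.null(events) && nrow(events) > 0) {
    ev <- events
    ev$category <- as.character(ev$category)
    ev <- ev %>% left_join(select(beliefs, -dplyr::any_of("n")), by = join_by)
    ev$weight <- ev$p * belief_multiplier
    weighted_events <- select(ev, "article_id", "exposure_time", "weight")
    series <- ev %>%
      mutate(time_bin = floor(.data$exposure_time / bin_width) * bin_width) %>%
      group_by(.data$article_id, .data$time_bin) %>%
      summarise(new_exposed = dplyr::n(), new_receptive = sum(.data$weight),
                .groups = "drop") %>%
      arrange(.data$article_id, .data$time_bin) %>%
      group_by(.data$article_id) %>%
      mutate(cum_exposed = cumsum(.data$new_exposed),
             cum_receptive = cumsum(.data$new_receptive)) %>%
      ungroup()
  }
  structure(list(totals = totals, contributions = contributions,
                 series = series, weighted_events = weighted_events,
                 bin_width = bin_width,
                 belief_multiplier = belief_multiplier),
            class = "receptivity_estimate")
}

#' @export
print.receptivity_estimate <- function(x, ...) {
  cat("<receptivity_estimate>\n")
  print(x$totals)
  invisible(x)
}

#' @rdname estimate_receptivity
#' @param ... Unused.
#' @export
tidy.receptivity_estimate <- function(x, ...) x$contributions

#' @rdname estimate_receptivity
#' @export
glance.receptivity_estimate <- function(x, ...) x$totals

#' Time-resolved receptivity metrics
#'
#' From a receptivity estimate with a time series, derives: the per-article
#' cumulative receptive curve normalized by its final value; the time at which
#' the normalized curve first reaches 0.5; and the fraction of newly exposed
#' users who are receptive, per hourly bin.
#'
#' @param estimate An [estimate_receptivity()] result carrying a time series.
#' @param bin_width Bin width in hours for the newly-exposed receptive
#'   fraction (default 1).
#' @return List with `normalized` (article_id, time_bin, cum_receptive_norm),
#'   `time_to_half` (article_id, t50, defined flag), and `new_receptive_frac`
#'   (article_id, hour_bin, frac_receptive, n_new).
#' @export
receptivity_metrics <- function(estimate, bin_width = 1) {
  stopifnot(inherits(estimate, "receptivity_estimate"))
  if (is.null(estimate$series)) {
    abort("The estimate carries no time series; build it from an exposure table with events.",
          class = "receptr_validation_error")
  }
  s <- estimate$series
  finals <- s %>%
    group_by(.data$article_id) %>%
    summarise(final = max(.data$cum_receptive), .groups = "drop")
  normalized <- s %>%
    left_join(finals, by = "article_id") %>%
    mutate(cum_receptive_norm = ifelse(.data$final > 0,
                                       .data$cum_receptive / .data$final,
                                       NA_real_)) %>%
    select("article_id", "time_bin", "cum_receptive_norm")
  undefined <- finals$article_id[finals$final <= 0]
  if (length(undefined) > 0) {
    warn(sprintf(
      "receptivity_metrics: zero total receptive audience for article(s) %s; normalized curve undefined.",
      paste(undefined, collapse = ", ")))
  }
  # Time-to-50% from exact event times: the earliest exposure time at which
  # the cumulative receptive weight reaches half of the article's total.
  time_to_half <- estimate$weighted_events %>%
    arrange(.data$article_id, .data$exposure_time) %>%
    group_by(.data$article_id) %>%
    summarise(
      t50 = {
        total <- sum(.data$weight)
        if (total <= 0) NA_real_ else
          .data$exposure_time[which(cumsum(.data$weight) >= total / 2)[1]]
      },
      .groups = "drop") %>%
    mutate(defined = !is.na(.data$t50))
  new_frac <- estimate$series %>%
    mutate(hour_bin = floor(.data$time_bin / bin_width) * bin_width) %>%
    group_by(.data$article_id, .data$hour_bin) %>%
    summarise(n_new = sum(.data$new_exposed),
              frac_receptive = sum(.data$new_receptive) /
                sum(.data$new_exposed),
              .groups = "drop")
  list(normalized = normalized, time_to_half = time_to_half,
       new_receptive_frac = new_frac)
}
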