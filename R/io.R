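# Readers and writers for the package's tabular formats (comma-separated,
# UTF-8, header row), dataset loading with row-level validation, and run
# manifests.

tweet_cols <- readr::cols(
  tweet_id = readr::col_character(), user_id = readr::col_character(),
  article_id = readr::col_character(), kind = readr::col_character(),
  root_tweet_id = readr::col_character(), .default = readr::col_guess())

#' Read package input tables
#'
#' `read_tweets()` accepts either a numeric `time` column (hours since the
#' article's first share) or a `timestamp` column (ISO-8601), which is
#' converted to hours from each article's first share on load.
#'
#' @param path File path (CSV with header).
#' @return A tibble in the corresponding module's input format.
#' @export
read_tweets <- function(path) {
  raw <- readr::read_csv(path, col_types = tweet_cols, progress = FALSE)
  if (!"time" %in% names(raw)) {
    if (!"timestamp" %in% names(raw)) {
      abort("Tweet table needs a `time` (hours) or `timestamp` (ISO-8601) column.",
            class = "receptr_schema_error")
    }
    ts <- as.POSIXct(raw$timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
    if (any(is.na(ts))) {
      abort(sprintf("Unparseable timestamp(s) at row(s): %s",
                    paste(head(which(is.na(ts)), 5), collapse = ", ")),
            class = "receptr_schema_error")
    }
    raw <- raw %>%
      group_by(.data$article_id) %>%
      mutate(time = as.numeric(difftime(ts[dplyr::cur_group_rows()],
                                        min(ts[dplyr::cur_group_rows()]),
                                        units = "hours"))) %>%
      ungroup() %>%
      select(-"timestamp")
  }
  validate_tweets(raw)
}

#' @rdname read_tweets
#' @export
read_follow_edges <- function(path) {
  edges <- readr::read_csv(path, col_types = readr::cols(
    follower_id = readr::col_character(),
    followee_id = readr::col_character()), progress = FALSE)
  assert_columns(edges, c("follower_id", "followee_id"), "edges")
  edges
}

#' @rdname read_tweets
#' @export
read_ideology_scores <- function(path) {
  scores <- readr::read_csv(path, col_types = readr::cols(
    user_id = readr::col_character(), score = readr::col_double()),
    progress = FALSE)
  assert_columns(scores, c("user_id", "score"), "scores")
  bad <- which(!is.finite(scores$score))
  if (length(bad) > 0) {
    abort(sprintf("Non-finite ideology score(s) at row(s): %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "receptr_validation_error")
  }
  dup <- which(duplicated(scores$user_id))
  if (length(dup) > 0) {
    abort(sprintf("Duplicate user_id in score table at row(s): %s",
                  paste(head(dup, 5), collapse = ", ")),
          class = "receptr_schema_error")
  }
  scores
}

#' @rdname read_tweets
#' @export
read_survey <- function(path) {
  resp <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  assert_columns(resp, c("respondent_id", "article_id", "rating", "category"),
                 "survey")
  dup <- which(duplicated(resp[, c("respondent_id", "article_id")]))
  if (length(dup) > 0) {
    abort(sprintf("Duplicated (respondent, article) survey row(s) at: %s",
                  paste(head(dup, 5), collapse = ", ")),
          class = "receptr_schema_error")
  }
  resp
}

#' @rdname read_tweets
#' @export
read_articles <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    article_id = readr::col_character(), .default = readr::col_guess()),
    progress = FALSE)
}

#' Load and validate a complete input bundle
#'
#' Reads the tweet table, follow-edge list, partial score table, survey table,
#' and (if present) article metadata from a directory produced by
#' [make_demo_dataset()] or laid out the same way. Tweets referencing users
#' absent from the follow graph are retained with empty follower sets (a
#' warning reports how many).
#'
#' @param dir Directory containing `tweets.csv`, `follow_edges.csv`,
#'   `ideology_scores.csv`, `survey.csv`, and optionally `articles.csv`.
#' @return List with `tweets`, `graph` ([social_graph()]), `scores`, `survey`,
#'   `articles` (or NULL).
#' @export
load_dataset <- function(dir) {
  need <- c(tweets = "tweets.csv", edges = "follow_edges.csv",
            scores = "ideology_scores.csv", survey = "survey.csv")
  paths <- file.path(dir, need)
  missing <- !file.exists(paths)
  if (any(missing)) {
    abort(sprintf("Missing input file(s): %s",
                  paste(need[missing], collapse = ", ")),
          class = "receptr_schema_error")
  }
  tweets <- read_tweets(paths[1])
  graph <- social_graph(read_follow_edges(paths[2]))
  scores <- read_ideology_scores(paths[3])
  survey <- read_survey(paths[4])
  art_path <- file.path(dir, "articles.csv")
  articles <- if (file.exists(art_path)) read_articles(art_path) else NULL
  unknown <- setdiff(tweets$user_id, graph$edges$followee_id)
  if (length(unknown) > 0) {
    warn(sprintf(
      "%d tweeting user(s) have no followers in the edge list; treated as having empty follower sets.",
      length(unknown)))
  }
  list(tweets = tweets, graph = graph, scores = scores, survey = survey,
       articles = articles)
}

#' Write pipeline results
#'
#' Writes the exposure table (long counts + time series), belief table,
#' per-article receptivity summary with per-category contributions, the
#' exposure event stream, and a manifest recording the seed and package
#' version. Column order and row sort are deterministic and every file
#' round-trips through `readr::read_csv()`.
#'
#' @param run A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest (defaults to the run's).
#' @return Invisibly, the named list of paths written.
#' @export
write_results <- function(run, dir, seed = run$seed) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    exposure_counts = file.path(dir, "exposure_counts.csv"),
    exposure_series = file.path(dir, "exposure_series.csv"),
    events = file.path(dir, "exposure_events.csv"),
    belief = file.path(dir, "belief_table.csv"),
    receptivity = file.path(dir, "receptivity.csv"),
    contributions = file.path(dir, "receptivity_contributions.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  counts <- run$exposures$counts %>%
    mutate(category = as.character(.data$category)) %>%
    arrange(.data$article_id, .data$category)
  readr::write_csv(counts, paths$exposure_counts)
  readr::write_csv(arrange(run$exposures$series, .data$article_id,
                           .data$time_bin), paths$exposure_series)
  readr::write_csv(run$exposures$events %>%
                     mutate(category = as.character(.data$category)) %>%
                     arrange(.data$article_id, .data$exposure_time,
                             .data$user_id),
                   paths$events)
  readr::write_csv(as_tibble(run$belief) %>%
                     mutate(category = as.character(.data$category)) %>%
                     arrange(.data$article_id, .data$category), paths$belief)
  readr::write_csv(arrange(run$estimate$totals, .data$article_id),
                   paths$receptivity)
  readr::write_csv(arrange(run$estimate$contributions, .data$article_id,
                           .data$category), paths$contributions)
  manifest <- list(
    package = "receptr",
    version = as.character(utils::packageVersion("receptr")),
    seed = seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = lapply(paths[names(paths) != "manifest"], basename)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE)
  invisible(paths)
}

#' Write an intervention experiment to disk
#'
#' @param result An [run_intervention_experiment()] result.
#' @param dir Output directory.
#' @return Invisibly, paths of the per-run table and the aggregate summary.
#' @export
write_intervention_results <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(runs = file.path(dir, "intervention_runs.csv"),
                summary = file.path(dir, "intervention_summary.csv"))
  readr::write_csv(as_tibble(result) %>%
                     arrange(.data$intervention, .data$t_int,
                             .data$article_id, .data$replicate),
                   paths$runs)
  readr::write_csv(summary(result), paths$summary)
  invisible(paths)
}
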