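# End-to-end orchestration: reconstruct cascades, fit the two-stage ideology
# model, assign a score to every sharer and follower, compute exposures and
# survey belief rates, and estimate receptive exposure per article.

#' Fit follower-ideology models for every sharer
#'
#' Fits one skew-normal follower model per unique sharer in the cascade set,
#' using that sharer's followers with known scores; sharers with no scored
#' followers get the population-prior fallback.
#'
#' @param cascades A [build_cascades()] result.
#' @param graph A [social_graph()].
#' @param known_scores Tibble `user_id`, `score` of known ideology scores.
#' @param pop A fitted [fit_population_prior()].
#' @param seed Optional integer seed.
#' @param needed_only Skip sharers all of whose followers already have known
#'   scores (their model would never be sampled from); default `TRUE`.
#' @param ... Sampler settings passed to [fit_follower_distribution()].
#' @return Named list of `follower_ideology_model`, one per sharer (skipped
#'   sharers hold `NULL`).
#' @export
fit_sharer_models <- function(cascades, graph, known_scores, pop, seed = NULL,
                              needed_only = TRUE, ...) {
  sharers <- sort(unique(cascades$user_id))
  score_map <- setNames(known_scores$score, known_scores$user_id)
  models <- purrr::map(seq_along(sharers), function(i) {
    u <- sharers[i]
    fols <- followers(graph, u)
    vals <- score_map[fols]
    known <- !is.na(vals)
    if (needed_only && length(fols) > 0 && all(known)) return(NULL)
    fit_follower_distribution(unname(vals[known]), pop, user_id = u,
                              seed = derive_seed(seed, i), ...)
  })
  setNames(models, sharers)
}

#' Assign an ideology score to every exposed-or-sharing user
#'
#' Builds the per-run score assignment used by all downstream consumers:
#' sharers get known / friend-mean / population-mean scores
#' ([impute_tweeter_score()]); followers keep their known score when one
#' exists, and otherwise are sampled once from the follower model of the
#' sharer they follow ([sample_missing_follower_scores()]). A follower of
#' several sharers is sampled from the model of the sharer with the earliest
#' tweet, so the assignment is deterministic given the seed.
#'
#' @param cascades A [build_cascades()] result.
#' @param graph A [social_graph()].
#' @param known_scores Tibble `user_id`, `score`.
#' @param pop A fitted [fit_population_prior()].
#' @param models Named list from [fit_sharer_models()].
#' @param seed Optional integer seed.
#' @param posterior_predictive Passed to [sample_missing_follower_scores()].
#' @return Tibble `user_id`, `score`, `source` (known / friend_mean /
#'   population / sampled) covering every sharer and every follower of a
#'   sharer.
#' @export
assign_follower_scores <- function(cascades, graph, known_scores, pop, models,
                                   seed = NULL,
                                   posterior_predictive = FALSE) {
  sharer_first_time <- cascades %>%
    as_tibble() %>%
    group_by(.data$user_id) %>%
    summarise(first_time = min(.data$time), .groups = "drop") %>%
    arrange(.data$first_time, .data$user_id)
  sharer_scores <- impute_tweeter_score(sharer_first_time$user_id,
                                        known_scores, graph, pop) %>%
    rename(source = "method")

  score_map <- setNames(known_scores$score, known_scores$user_id)
  assigned <- sharer_scores$user_id
  out <- list(sharer_scores)
  for (i in seq_len(nrow(sharer_first_time))) {
    u <- sharer_first_time$user_id[i]
    fols <- setdiff(followers(graph, u), assigned)
    if (length(fols) == 0) next
    known <- !is.na(score_map[fols])
    rows_known <- tibble(user_id = fols[known],
                         score = unname(score_map[fols[known]]),
                         source = "known")
    fols_unknown <- fols[!known]
    rows_sampled <- NULL
    if (length(fols_unknown) > 0) {
      model <- models[[u]]
      if (is.null(model)) {
        abort(sprintf("No follower model for sharer %s.", u),
              class = "receptr_schema_error")
      }
      draws <- sample_missing_follower_scores(
        model, length(fols_unknown), seed = derive_seed(seed, 7000L + i),
        posterior_predictive = posterior_predictive)
      rows_sampled <- tibble(user_id = fols_unknown, score = draws,
                             source = "sampled")
    }
    out[[length(out) + 1]] <- bind_rows(rows_known, rows_sampled)
    assigned <- c(assigned, fols)
  }
  bind_rows(out)
}

#' Run the full exposure-and-receptivity pipeline
#'
#' From raw inputs to per-article receptive-exposure estimates: reconstructs
#' cascades, fits the population and per-sharer ideology models, assigns
#' scores, simulates exposure under the delay model, computes survey belief
#' rates, and evaluates r_j.
#'
#' @param data Input bundle as returned by [load_dataset()]: `tweets`,
#'   `graph`, `scores`, `survey` (and optionally `articles`).
#' @param seed Integer seed for all stochastic stages.
#' @param model A [delay_model()].
#' @param sampler Sampler settings: list with `pop` and `follower` lists of
#'   `chains`, `warmup`, `draws` overrides.
#' @param bin_width Time-series resolution in hours (default 0.5).
#' @param on_empty_cell Passed to [compute_belief_table()].
#' @return List (class `receptr_run`) with every intermediate product:
#'   `cascades`, `pop`, `models`, `scores`, `exposures`, `belief`, `estimate`,
#'   and `metrics`.
#' @export
run_pipeline <- function(data, seed = 1L, model = delay_model(),
                         sampler = list(), bin_width = 0.5,
                         on_empty_cell = "error") {
  pop_set <- utils::modifyList(list(chains = 2, warmup = 1000, draws = 3000),
                               sampler$pop %||% list())
  fol_set <- utils::modifyList(list(chains = 4, warmup = 500, draws = 2000),
                               sampler$follower %||% list())
  cascades <- build_cascades(data$tweets, data$graph)
  pop <- fit_population_prior(data$scores, chains = pop_set$chains,
                              warmup = pop_set$warmup, draws = pop_set$draws,
                              seed = derive_seed(seed, 1L))
  models <- fit_sharer_models(cascades, data$graph, data$scores, pop,
                              seed = derive_seed(seed, 2L),
                              chains = fol_set$chains,
                              warmup = fol_set$warmup, draws = fol_set$draws)
  scores <- assign_follower_scores(cascades, data$graph, data$scores, pop,
                                   models, seed = derive_seed(seed, 3L))
  events <- compute_exposures(cascades, data$graph, scores, model = model,
                              seed = derive_seed(seed, 4L))
  exposures <- tabulate_exposures(events, bin_width = bin_width)
  belief <- compute_belief_table(data$survey, on_empty_cell = on_empty_cell)
  estimate <- estimate_receptivity(exposures, belief, bin_width = bin_width)
  metrics <- if (nrow(events) > 0) receptivity_metrics(estimate) else NULL
  structure(list(cascades = cascades, pop = pop, models = models,
                 scores = scores, exposures = exposures, belief = belief,
                 estimate = estimate, metrics = metrics, seed = seed),
            class = "receptr_run")
}

#' @export
print.receptr_run <- function(x, ...) {
  cat("<receptr_run>\n")
  print(x$estimate$totals)
  invisible(x)
}

#' Intervention-ready bundle from a pipeline run
#'
#' @param run A [run_pipeline()] result.
#' @param data The input bundle the run was computed from.
#' @return List with `cascades`, `graph`, `scores`, `belief` as required by
#'   [run_intervention_experiment()].
#' @export
intervention_bundle <- function(run, data) {
  list(cascades = run$cascades, graph = data$graph, scores = run$scores,
       belief = run$belief)
}
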