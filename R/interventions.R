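# Counterfactual platform interventions with deployment delay t_int (hours
# after an article's first share):
#   * fact_check_label  — each retweet/quote after t_int removed with p = 0.25
#                         (with its whole descendant subtree) and belief rates
#                         of post-t_int exposures multiplied by 0.83;
#   * sharing_friction  — retweet/quote removal with p = 0.75;
#   * visibility_light/heavy — candidate exposure events after t_int dropped
#                         with p = 0.25 / 0.75 before deduplication;
#   * none              — the paired baseline.
# Baselines share the replicate seed with the intervention run, so reported
# reductions are paired Monte-Carlo comparisons.

INTERVENTION_TYPES <- c("none", "fact_check_label", "sharing_friction",
                        "visibility_light", "visibility_heavy")

#' Intervention configuration
#'
#' Bundles an intervention type with its rates and deployment delay. Defaults
#' follow the literature-derived values used in the simulations: fact-check
#' labels make a retweet 25% less likely and belief 17% less likely
#' (multiplier 0.83); sharing friction makes a retweet 75% less likely;
#' visibility reduction drops 25% (light) or 75% (heavy) of candidate
#' exposures.
#'
#' @param type One of `"none"`, `"fact_check_label"`, `"sharing_friction"`,
#'   `"visibility_light"`, `"visibility_heavy"`.
#' @param t_int Deployment delay in hours (>= 0) after the article's first
#'   share.
#' @param retweet_removal_prob,belief_multiplier,visibility_removal_prob
#'   Override the per-type defaults (all probabilities in `[0, 1]`).
#' @param replicates Simulation replicates per (article, delay) (default 10).
#' @param seed Base seed; replicate r runs under `seed + r`.
#' @return An `intervention_config` list.
#' @export
intervention_config <- function(type = "none", t_int = 0,
                                retweet_removal_prob = NULL,
                                belief_multiplier = NULL,
                                visibility_removal_prob = NULL,
                                replicates = 10, seed = NULL) {
  type <- match.arg(type, INTERVENTION_TYPES)
  defaults <- list(
    none = c(rt = 0, bm = 1, vis = 0),
    fact_check_label = c(rt = 0.25, bm = 0.83, vis = 0),
    sharing_friction = c(rt = 0.75, bm = 1, vis = 0),
    visibility_light = c(rt = 0, bm = 1, vis = 0.25),
    visibility_heavy = c(rt = 0, bm = 1, vis = 0.75)
  )[[type]]
  cfg <- list(
    type = type,
    t_int = t_int,
    retweet_removal_prob = retweet_removal_prob %||% unname(defaults["rt"]),
    belief_multiplier = belief_multiplier %||% unname(defaults["bm"]),
    visibility_removal_prob = visibility_removal_prob %||%
      unname(defaults["vis"]),
    replicates = as.integer(replicates),
    seed = seed
  )
  if (!is.numeric(t_int) || t_int < 0) {
    abort("`t_int` must be >= 0 hours.", class = "receptr_validation_error")
  }
  assert_prob(cfg$retweet_removal_prob, "retweet_removal_prob")
  assert_prob(cfg$belief_multiplier, "belief_multiplier")
  assert_prob(cfg$visibility_removal_prob, "visibility_removal_prob")
  if (cfg$replicates < 1) {
    abort("`replicates` must be >= 1.", class = "receptr_validation_error")
  }
  structure(cfg, class = "intervention_config")
}

#' Remove retweets (and their subtrees) under a sharing intervention
#'
#' Each retweet or quote tweet with `time > t_int` is independently removed
#' with probability `removal_prob`; removing a tweet also removes every
#' descendant in the reconstructed cascade, since a retweet that never
#' happened cannot itself be retweeted. Original tweets are never removed.
#'
#' @param cascades A [build_cascades()] result.
#' @param removal_prob Removal probability in `[0, 1]`.
#' @param t_int Deployment delay in hours.
#' @param seed Optional integer seed.
#' @return The surviving cascade set (same columns, subset of rows).
#' @export
prune_cascade <- function(cascades, removal_prob, t_int = 0, seed = NULL) {
  assert_prob(removal_prob, "removal_prob")
  assert_columns(cascades, c("tweet_id", "kind", "time", "parent_tweet_id"),
                 "cascades")
  if (removal_prob == 0) return(cascades)
  eligible <- cascades$kind != "original" & cascades$time > t_int
  hit <- with_seed_or_current(seed, {
    out <- logical(nrow(cascades))
    out[eligible] <- runif(sum(eligible)) < removal_prob
    out
  })
  removed <- cascades$tweet_id[hit]
  if (length(removed) > 0) {
    # Propagate removal down the forest: children of removed tweets die too.
    repeat {
      orphan <- !cascades$tweet_id %in% removed &
        cascades$parent_tweet_id %in% removed
      if (!any(orphan)) break
      removed <- c(removed, cascades$tweet_id[orphan])
    }
  }
  cascades[!cascades$tweet_id %in% removed, , drop = FALSE]
}

#' Discount belief rates for post-intervention exposures
#'
#' Under fact-check labeling, users exposed after the label is deployed are
#' less likely to believe the article: exposure events with
#' `exposure_time > t_int` get their category belief rate multiplied by
#' `belief_multiplier`; earlier exposures keep the undiscounted rate. With
#' `global = TRUE` the discount applies to all events regardless of timing
#' (sensitivity analysis).
#'
#' @param p A [compute_belief_table()] result (or compatible tibble).
#' @param events Deduplicated exposure events from [compute_exposures()].
#' @param belief_multiplier Multiplier in `[0, 1]`.
#' @param t_int Deployment delay in hours.
#' @param global Discount pre-intervention exposures too?
#' @return The events tibble with columns `p` (the category/article belief
#'   rate), `discounted` flag, and `effective_p`.
#' @export
discount_belief <- function(p, events, belief_multiplier, t_int = 0,
                            global = FALSE) {
  assert_prob(belief_multiplier, "belief_multiplier")
  beliefs <- as_belief_tbl(p)
  assert_columns(events, c("article_id", "category", "exposure_time"),
                 "events")
  ev <- as_tibble(events)
  ev$category <- as.character(ev$category)
  beliefs$category <- as.character(beliefs$category)
  per_article <- all(ev$article_id %in% beliefs$article_id)
  join_by <- if (per_article) c("article_id", "category") else "category"
  if (!per_article) beliefs$article_id <- NULL
  ev <- ev %>% left_join(select(beliefs, -dplyr::any_of("n")), by = join_by)
  if (any(is.na(ev$p))) {
    abort("Some exposure events have no matching belief rate.",
          class = "receptr_schema_error")
  }
  ev %>%
    mutate(discounted = global | .data$exposure_time > t_int,
           effective_p = if_else(.data$discounted,
                                 .data$p * belief_multiplier, .data$p))
}

# One simulation pass: prune -> expose (with optional visibility filter)
# -> discount -> receptive total. Returns exposed and receptive counts.
simulate_once <- function(cascades, graph, scores, belief, cfg, model, seed,
                          include_sharers = FALSE) {
  surv <- prune_cascade(cascades, cfg$retweet_removal_prob, cfg$t_int,
                        seed = derive_seed(seed, 11L))
  filt <- if (cfg$visibility_removal_prob > 0) {
    list(prob = cfg$visibility_removal_prob, t_int = cfg$t_int)
  } else {
    NULL
  }
  events <- compute_exposures(surv, graph, scores, model = model,
                              visibility_filter = filt,
                              include_sharers = include_sharers,
                              seed = derive_seed(seed, 12L))
  if (nrow(events) == 0) {
    return(tibble(article_id = unique(cascades$article_id), exposed = 0L,
                  receptive = 0))
  }
  weighted <- discount_belief(belief, events, cfg$belief_multiplier,
                              cfg$t_int)
  weighted %>%
    group_by(.data$article_id) %>%
    summarise(exposed = dplyr::n(), receptive = sum(.data$effective_p),
              .groups = "drop")
}

#' Run a replicated intervention experiment
#'
#' For each intervention type, deployment delay, and replicate, simulates the
#' intervention on every article and pairs it with a no-intervention baseline
#' run under the same replicate seed, reporting the percent reduction in
#' receptive exposure 100 * (1 - r_int / r_base).
#'
#' @param bundle List with `cascades` ([build_cascades()] result), `graph`
#'   ([social_graph()]), `scores` (per-user ideology tibble covering all
#'   followers, see [assign_follower_scores()]), and `belief`
#'   ([compute_belief_table()] result).
#' @param types Character vector of intervention types to run (default all
#'   four active types).
#' @param delays Numeric vector of deployment delays t_int in hours.
#' @param replicates Replicates per (article, type, delay) (default 10).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param model A [delay_model()].
#' @param paired Use the same replicate seed for baseline and intervention
#'   (default `TRUE`); unpaired mode draws independent baselines.
#' @param ... Overrides passed to [intervention_config()] (e.g.
#'   `belief_multiplier`).
#' @return An `intervention_result`: tibble with one row per (article, type,
#'   delay, replicate) holding exposed/receptive counts, baseline
#'   counterparts, and `pct_reduction`. Use [summary()] / [glance()] for the
#'   mean and central 90% band.
#' @export
run_intervention_experiment <- function(bundle, types = c("fact_check_label",
                                                          "sharing_friction",
                                                          "visibility_light",
                                                          "visibility_heavy"),
                                        delays = 0, replicates = 10,
                                        seed = 1L, model = delay_model(),
                                        paired = TRUE, ...) {
  for (nm in c("cascades", "graph", "scores", "belief")) {
    if (is.null(bundle[[nm]])) {
      abort(sprintf("`bundle` is missing `%s`.", nm),
            class = "receptr_schema_error")
    }
  }
  types <- match.arg(types, INTERVENTION_TYPES, several.ok = TRUE)
  rows <- list()
  base_cfg <- intervention_config("none", t_int = 0)
  base_cache <- new.env(parent = emptyenv())
  get_baseline <- function(base_seed) {
    key <- as.character(base_seed)
    if (is.null(base_cache[[key]])) {
      base_cache[[key]] <- simulate_once(bundle$cascades, bundle$graph,
                                         bundle$scores, bundle$belief,
                                         base_cfg, model, base_seed)
    }
    base_cache[[key]]
  }
  for (type in types) {
    for (d in delays) {
      cfg <- intervention_config(type = type, t_int = d,
                                 replicates = replicates, seed = seed, ...)
      for (r in seq_len(replicates)) {
        rep_seed <- derive_seed(seed, r)
        base_seed <- if (paired) rep_seed else derive_seed(seed, 100000L + r)
        int_res <- simulate_once(bundle$cascades, bundle$graph, bundle$scores,
                                 bundle$belief, cfg, model, rep_seed)
        base_res <- get_baseline(base_seed)
        merged <- base_res %>%
          rename(baseline_exposed = "exposed",
                 baseline_receptive = "receptive") %>%
          left_join(int_res, by = "article_id") %>%
          mutate(exposed = dplyr::coalesce(.data$exposed, 0L),
                 receptive = dplyr::coalesce(.data$receptive, 0),
                 intervention = type, t_int = d, replicate = r,
                 pct_reduction = ifelse(
                   .data$baseline_receptive > 0,
                   100 * (1 - .data$receptive / .data$baseline_receptive),
                   NA_real_))
        rows[[length(rows) + 1]] <- merged
      }
    }
  }
  out <- bind_rows(rows) %>%
    select("article_id", "intervention", "t_int", "replicate", "exposed",
           "receptive", "baseline_exposed", "baseline_receptive",
           "pct_reduction")
  structure(out, class = c("intervention_result", class(out)),
            seed = seed, paired = paired)
}

#' Summarise an intervention experiment
#'
#' Mean percent reduction in receptive exposure with the central 90% interval
#' across replicates and articles, per intervention type and delay.
#'
#' @param object An [run_intervention_experiment()] result.
#' @param ... Unused.
#' @return Tibble with `intervention`, `t_int`, `mean_pct_reduction`,
#'   `q05`, `q95`, and `n_runs`.
#' @export
summary.intervention_result <- function(object, ...) {
  object %>%
    as_tibble() %>%
    filter(!is.na(.data$pct_reduction)) %>%
    group_by(.data$intervention, .data$t_int) %>%
    summarise(mean_pct_reduction = mean(.data$pct_reduction),
              q05 = quantile(.data$pct_reduction, 0.05),
              q95 = quantile(.data$pct_reduction, 0.95),
              n_runs = dplyr::n(), .groups = "drop")
}

#' @rdname summary.intervention_result
#' @param x An `intervention_result`.
#' @export
glance.intervention_result <- function(x, ...) summary(x)
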