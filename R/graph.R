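# Directed follow graph stored as an edge table plus follower/friend indexes.
# An edge (follower_id -> followee_id) means follower_id follows followee_id,
# so followee_id's tweets can appear in follower_id's feed.

#' Build a social graph from a follow edge list
#'
#' @param edges Data frame with columns `follower_id`, `followee_id`
#'   (follower follows followee). Self-edges are dropped with a warning;
#'   duplicate edges are collapsed.
#' @return A `social_graph` object with fast `followers()`/`friends()` lookup.
#' @examples
#' g <- social_graph(tibble::tibble(follower_id = c("b", "c"),
#'                                  followee_id = c("a", "a")))
#' followers(g, "a")
#' friends(g, "b")
#' @export
social_graph <- function(edges) {
  assert_columns(edges, c("follower_id", "followee_id"), "edges")
  edges <- tibble(follower_id = as.character(edges$follower_id),
                  followee_id = as.character(edges$followee_id))
  self <- edges$follower_id == edges$followee_id
  if (any(self)) {
    warn(sprintf("Dropping %d self-follow edge(s).", sum(self)))
    edges <- edges[!self, ]
  }
  edges <- distinct(edges)
  structure(
    list(edges = edges,
         followers_idx = split(edges$follower_id, edges$followee_id),
         friends_idx = split(edges$followee_id, edges$follower_id)),
    class = "social_graph")
}

#' @export
print.social_graph <- function(x, ...) {
  cat(sprintf("<social_graph> %d edges, %d users with followers, %d users with friends\n",
              nrow(x$edges), length(x$followers_idx), length(x$friends_idx)))
  invisible(x)
}

#' Followers and friends of a user
#'
#' @param graph A [social_graph()].
#' @param user_id Single user id.
#' @return Character vector of user ids (empty if the user is unknown).
#' @export
followers <- function(graph, user_id) {
  stopifnot(inherits(graph, "social_graph"))
  graph$followers_idx[[as.character(user_id)]] %||% character(0)
}

#' @rdname followers
#' @export
friends <- function(graph, user_id) {
  stopifnot(inherits(graph, "social_graph"))
  graph$friends_idx[[as.character(user_id)]] %||% character(0)
}
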