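#' Maximum bipartite matching (Hopcroft-Karp)
#'
#' Computes a maximum-cardinality matching in a bipartite graph given as
#' an edge list between `n_left` left vertices and `n_right` right
#' vertices, using the Hopcroft-Karp algorithm: repeated BFS phases find
#' the shortest augmenting-path length, then a DFS sweep augments along
#' a maximal set of vertex-disjoint shortest paths. Worst-case
#' O(E sqrt(V)).
#'
#' Vertices are processed in index order, so the returned matching is
#' deterministic for a given edge list.
#'
#' @param edges integer matrix with two columns `(i, j)`: an edge
#'   between left vertex `i` and right vertex `j`. Duplicate edges are
#'   tolerated and ignored.
#' @param n_left,n_right number of vertices on each side.
#' @return Integer matrix of matched pairs (columns `i`, `j`); zero rows
#'   for an empty graph.
#' @examples
#' max_bipartite_matching(rbind(c(1, 1), c(1, 2), c(2, 1)), 2, 2)
#' @export
max_bipartite_matching <- function(edges, n_left, n_right) {
  n_left <- as.integer(n_left); n_right <- as.integer(n_right)
  if (is.null(edges) || NROW(edges) == 0 || n_left == 0 || n_right == 0) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  edges <- matrix(as.integer(edges), ncol = 2)
  stopifnot(all(edges[, 1] >= 1), all(edges[, 1] <= n_left),
            all(edges[, 2] >= 1), all(edges[, 2] <= n_right))
  edges <- unique(edges)
  # adjacency lists for left vertices, neighbor order by right index
  o <- order(edges[, 1], edges[, 2])
  edges <- edges[o, , drop = FALSE]
  adj <- split(edges[, 2], factor(edges[, 1], levels = seq_len(n_left)))

  INF <- .Machine$integer.max
  match_l <- integer(n_left)   # 0 = unmatched
  match_r <- integer(n_right)
  dist <- integer(n_left)

  bfs <- function() {
    queue <- integer(0)
    for (u in seq_len(n_left)) {
      if (match_l[u] == 0L) {
        dist[u] <<- 0L
        queue <- c(queue, u)
      } else dist[u] <<- INF
    }
    found <- FALSE
    head <- 1L
    while (head <= length(queue)) {
      u <- queue[head]; head <- head + 1L
      for (v in adj[[u]]) {
        w <- match_r[v]
        if (w == 0L) {
          found <- TRUE
        } else if (dist[w] == INF) {
          dist[w] <<- dist[u] + 1L
          queue <- c(queue, w)
        }
      }
    }
    found
  }

  dfs <- function(u) {
    for (v in adj[[u]]) {
      w <- match_r[v]
      if (w == 0L || (dist[w] == dist[u] + 1L && dfs(w))) {
        match_l[u] <<- v
        match_r[v] <<- u
        return(TRUE)
      }
    }
    dist[u] <<- INF
    FALSE
  }

  while (bfs()) {
    for (u in seq_len(n_left)) {
      if (match_l[u] == 0L) dfs(u)
    }
  }

  i <- which(match_l != 0L)
  cbind(i = i, j = match_l[i])
}
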