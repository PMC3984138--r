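# Independent oracles used across tests. These deliberately share no
# code with the implementation: naive loops, recursion and closed forms.

# naive k-nearest neighbors: full scan, sort by (distance, index)
brute_knn <- function(Q, x, k) {
  d <- numeric(nrow(Q))
  for (j in seq_len(nrow(Q)))
    d[j] <- sqrt((Q[j, 1] - x[1])^2 + (Q[j, 2] - x[2])^2)
  o <- order(d, seq_along(d))
  o[seq_len(min(k, length(o)))]
}

# maximum bipartite matching by exhaustive recursion over left vertices
brute_max_matching <- function(edges, n_left, n_right) {
  adj <- vector("list", n_left)
  if (NROW(edges) > 0) {
    edges <- matrix(as.integer(edges), ncol = 2)
    for (r in seq_len(nrow(edges)))
      adj[[edges[r, 1]]] <- union(adj[[edges[r, 1]]], edges[r, 2])
  }
  rec <- function(u, used) {
    if (u > n_left) return(0L)
    best <- rec(u + 1L, used)           # leave u unmatched
    for (v in adj[[u]]) {
      if (!used[v]) {
        used[v] <- TRUE
        best <- max(best, 1L + rec(u + 1L, used))
        used[v] <- FALSE
      }
    }
    best
  }
  rec(1L, logical(n_right))
}

# exhaustive translation + assignment search: the maximum number of
# one-to-one pairs within delta achievable at any pair-generated
# candidate translation within max_translation
brute_ppm_cardinality <- function(P, Q, delta, max_translation) {
  best <- 0L
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(nrow(Q))) {
      t <- c(Q[j, 1] - P[i, 1], Q[j, 2] - P[i, 2])
      if (sqrt(sum(t^2)) > max_translation) next
      edges <- NULL
      for (a in seq_len(nrow(P))) {
        for (b in seq_len(nrow(Q))) {
          d <- sqrt((P[a, 1] + t[1] - Q[b, 1])^2 +
                      (P[a, 2] + t[2] - Q[b, 2])^2)
          if (d <= delta) edges <- rbind(edges, c(a, b))
        }
      }
      if (!is.null(edges)) {
        card <- brute_max_matching(edges, nrow(P), nrow(Q))
        if (card > best) best <- card
      }
    }
  }
  best
}

# planted-correspondence fixture: n points, a copy shifted by `shift`
# with optional per-point jitter and extraneous points in either set
planted_sets <- function(n, shift = c(0, 0), jitter = 0,
                         extra_p = 0, extra_q = 0, span = 200,
                         min_gap = 8) {
  pts <- matrix(NA_real_, 0, 2)
  while (nrow(pts) < n + extra_p + extra_q) {
    cand <- runif(2, 0, span)
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >=
          min_gap)
      pts <- rbind(pts, cand)
  }
  base <- pts[seq_len(n), , drop = FALSE]
  q <- sweep(base, 2, -shift) +
    matrix(rnorm(2 * n, 0, jitter), n, 2)
  P <- rbind(base, pts[n + seq_len(extra_p), , drop = FALSE])
  Q <- rbind(q, pts[n + extra_p + seq_len(extra_q), , drop = FALSE])
  list(P = point_set(P), Q = point_set(Q),
       true_pairs = cbind(seq_len(n), seq_len(n)))
}
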