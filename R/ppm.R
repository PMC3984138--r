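#' Bias of a matching
#'
#' A matching may pair every point within the matching distance and
#' still be of poor quality: if all residual vectors `Q[j] - (P[i] + t)`
#' point the same way, the translation is systematically off and the
#' correspondence was likely found by sliding one set onto the wrong
#' neighbors. The bias quantifies this as the norm of the mean residual
#' vector, normalized by the matching distance `delta`: residuals
#' distributed uniformly in all directions average near zero and give a
#' bias near 0, while uniformly directed residuals at distance `delta`
#' give a bias near 1. Accepted matchings must stay below `max_bias`.
#'
#' @param pairs integer matrix of matched pairs (columns `i`, `j`).
#' @param P,Q `point_set`s (model and scene).
#' @param t the `translation` that produced the matching.
#' @param delta matching distance in pixels.
#' @param norm point-distance norm tag.
#' @return Non-negative scalar bias.
#' @export
matching_bias <- function(pairs, P, Q, t, delta, norm = "euclidean") {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) == 0) stop("bias is undefined for an empty matching")
  t <- as.numeric(t)
  rx <- Q[pairs[, 2], 1] - (P[pairs[, 1], 1] + t[1])
  ry <- Q[pairs[, 2], 2] - (P[pairs[, 1], 2] + t[2])
  vec_norm(c(mean(rx), mean(ry)), norm) / delta
}

#' Evaluate one candidate translation
#'
#' One loop body of the matcher: translate the model set `P` by `t`, for
#' each translated point collect up to `k` nearest scene points within
#' the matching distance `delta` as edges of a bipartite graph, take a
#' maximum bipartite matching, and test the three acceptance
#' constraints: matching ratio `|M| >= alpha * min(|P|, |Q|)`, bias
#' `<= max_bias`, and translation magnitude `<= max_translation`.
#'
#' @param P,Q `point_set`s (model and scene).
#' @param t a `translation` (or numeric `c(dx, dy)`).
#' @param params a [ppm_params()] object.
#' @param index optional prebuilt [build_neighbor_index()] over `Q`.
#' @return A `ppm_matching` with fields `pairs`, `translation`, `bias`
#'   and `accepted`.
#' @export
try_translation <- function(P, Q, t, params = ppm_params(), index = NULL) {
  if (!inherits(t, "translation")) t <- translation(t[1], t[2])
  n <- nrow(P); m <- nrow(Q)
  if (n == 0 || m == 0) return(empty_matching(n, m))
  if (is.null(index)) index <- build_neighbor_index(Q, params$norm)

  Pt <- translate_points(P, t)
  nn <- knn_query(index, Pt, k = params$k)
  keep <- nn$dist <= params$delta
  if (!any(keep)) {
    M <- empty_matching(n, m)
    M$translation <- t
    return(M)
  }
  ii <- row(nn$idx)[keep]
  jj <- nn$idx[keep]
  pairs <- max_bipartite_matching(cbind(ii, jj), n, m)

  b <- if (nrow(pairs) > 0)
    matching_bias(pairs, P, Q, t, params$delta, params$norm) else NA_real_
  accepted <- nrow(pairs) >= params$alpha * min(n, m) &&
    nrow(pairs) > 0 &&
    b <= params$max_bias &&
    translation_magnitude(t, params$norm) <= params$max_translation
  new_matching(pairs, t, b, accepted, n, m)
}

#' Point-pattern matching under translations
#'
#' Global search for a translation that puts subsets of two point sets
#' into one-to-one correspondence. Candidate translations are generated
#' from point pairs, `t = Q[j] - P[i]`, restricted to magnitudes within
#' `max_translation` (larger shifts could never be accepted, so pruning
#' them changes nothing); each candidate is evaluated with
#' [try_translation()]. Among all accepted candidates the best is
#' returned: largest matching, ties broken by smaller bias, then
#' smaller translation magnitude, then the lexicographically smallest
#' generating pair — making the result independent of iteration order.
#' If no candidate is accepted, an empty non-accepted matching is
#' returned: there is no match at the requested matching ratio.
#'
#' @inheritParams try_translation
#' @return A `ppm_matching`.
#' @examples
#' P <- point_set(c(10, 20, 30), c(10, 15, 5))
#' Q <- translate_points(P, c(2, 1))
#' M <- ppm_match(P, Q, ppm_params(delta = 0.5, max_translation = 3))
#' M$accepted; nrow(M$pairs)
#' @export
ppm_match <- function(P, Q, params = ppm_params()) {
  n <- nrow(P); m <- nrow(Q)
  if (n == 0 || m == 0) return(empty_matching(n, m))
  index <- build_neighbor_index(Q, params$norm)

  D <- cross_distances(P, Q, params$norm)
  cand <- which(D <= params$max_translation, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty_matching(n, m))
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]

  best <- NULL
  best_key <- NULL
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    t <- translation(Q[j, 1] - P[i, 1], Q[j, 2] - P[i, 2])
    M <- try_translation(P, Q, t, params, index)
    if (!M$accepted) next
    key <- c(-nrow(M$pairs), M$bias,
             translation_magnitude(t, params$norm))
    if (is.null(best) ||
        key[1] < best_key[1] ||
        (key[1] == best_key[1] && key[2] < best_key[2] - 1e-12) ||
        (key[1] == best_key[1] && abs(key[2] - best_key[2]) <= 1e-12 &&
           key[3] < best_key[3] - 1e-12)) {
      best <- M
      best_key <- key
    }
  }
  if (is.null(best)) return(empty_matching(n, m))
  best
}

#' Association estimate between two channels
#'
#' Runs the point-pattern matcher and converts the result into the
#' association estimate: the fraction of objects in each channel that
#' found a counterpart in the other channel, provided the matching was
#' accepted (sufficient matching ratio, low bias, moderate translation).
#' A failed or rejected matching — no correspondence at the requested
#' ratio, or only a drastic transformation, indicating a chance
#' correspondence — yields association 0 for both channels. Values near
#' 1 indicate a high level of association; unlike pixel overlap, closely
#' located objects count even without direct overlap.
#'
#' @inheritParams try_translation
#' @return A list of class `association_result` with elements
#'   `assoc_ch1`, `assoc_ch2`, `matching`, `n_objects_ch1`,
#'   `n_objects_ch2`.
#' @export
association <- function(P, Q, params = ppm_params()) {
  M <- ppm_match(P, Q, params)
  n1 <- nrow(P); n2 <- nrow(Q)
  k <- if (M$accepted) nrow(M$pairs) else 0L
  structure(list(
    assoc_ch1 = if (n1 > 0) k / n1 else 0,
    assoc_ch2 = if (n2 > 0) k / n2 else 0,
    matching = M,
    n_objects_ch1 = n1,
    n_objects_ch2 = n2
  ), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "<association: ch1 %.4f (%d obj), ch2 %.4f (%d obj), %d pairs>\n",
    x$assoc_ch1, x$n_objects_ch1, x$assoc_ch2, x$n_objects_ch2,
    nrow(x$matching$pairs)))
  invisible(x)
}
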