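#' ICP registration parameters
#'
#' @param max_iterations maximum number of iterations (>= 1).
#' @param convergence_tol stop when the translation update norm falls
#'   below this value (pixels, > 0).
#' @param delta match radius in pixels for the final pairing; the same
#'   radius as the point-pattern matcher uses, for comparability.
#' @param biunique enforce one-to-one correspondences by keeping only
#'   mutually nearest pairs at each iteration.
#' @return A list of class `icp_params`.
#' @export
icp_params <- function(max_iterations = 50, convergence_tol = 1e-3,
                       delta = 4, biunique = TRUE) {
  stopifnot(max_iterations >= 1, convergence_tol > 0, delta > 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 delta = delta, biunique = isTRUE(biunique)),
            class = "icp_params")
}

#' Biunique iterated-closest-points registration baseline
#'
#' Translation-only ICP used as the registration baseline for
#' comparison with the point-pattern matcher. The initial translation
#' aligns the centroids of the two sets — an assumption that may or may
#' not hold for a given field of view, which is precisely the failure
#' mode the comparison probes. Each iteration pairs every translated
#' model point with its nearest scene point, optionally filters to
#' mutually nearest (biunique) pairs, and updates the translation by
#' the mean residual vector of the current pairs (the least-squares
#' optimum for fixed correspondences). Iteration stops when the update
#' norm drops below `convergence_tol` or after `max_iterations`. The
#' final matching keeps only pairs within `delta`.
#'
#' Being a local refinement, ICP converges to whatever optimum lies
#' near the centroid initialization; with many unique (unshared)
#' objects the initialization is biased and the pairing can fail
#' entirely, unlike the global translation search of [ppm_match()].
#'
#' @param P,Q non-empty `point_set`s.
#' @param params an [icp_params()] object.
#' @param norm point-distance norm tag.
#' @return A `ppm_matching` with an extra attribute `mse_history`:
#'   the mean squared residual over the current pair set at each
#'   iteration.
#' @export
icp_register <- function(P, Q, params = icp_params(), norm = "euclidean") {
  n <- nrow(P); m <- nrow(Q)
  if (n == 0 || m == 0) stop("icp_register requires non-empty point sets")

  t <- c(mean(Q[, 1]) - mean(P[, 1]), mean(Q[, 2]) - mean(P[, 2]))
  mse_history <- numeric(0)
  pairs <- NULL

  for (iter in seq_len(params$max_iterations)) {
    Pt <- cbind(P[, 1] + t[1], P[, 2] + t[2])
    D <- cross_distances(Pt, Q, norm)
    nn_q <- apply(D, 1, which.min)            # nearest Q for each P point
    if (params$biunique) {
      nn_p <- apply(D, 2, which.min)          # nearest P for each Q point
      mutual <- which(nn_p[nn_q] == seq_len(n))
      pairs <- cbind(i = mutual, j = nn_q[mutual])
    } else {
      pairs <- cbind(i = seq_len(n), j = nn_q)
    }
    rx <- Q[pairs[, 2], 1] - Pt[pairs[, 1], 1]
    ry <- Q[pairs[, 2], 2] - Pt[pairs[, 1], 2]
    mse_history <- c(mse_history, mean(rx^2 + ry^2))
    update <- c(mean(rx), mean(ry))
    t <- t + update
    if (vec_norm(update, norm) < params$convergence_tol) break
  }

  # final pairing at the converged translation, gated at delta
  Pt <- cbind(P[, 1] + t[1], P[, 2] + t[2])
  d <- vapply(seq_len(nrow(pairs)), function(r)
    point_distance(Pt[pairs[r, 1], ], Q[pairs[r, 2], ], norm), 0)
  pairs <- pairs[d <= params$delta, , drop = FALSE]

  tt <- translation(t[1], t[2])
  b <- if (nrow(pairs) > 0)
    matching_bias(pairs, P, Q, tt, params$delta, norm) else NA_real_
  M <- new_matching(pairs, tt, b, nrow(pairs) > 0, n, m)
  attr(M, "mse_history") <- mse_history
  M
}
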