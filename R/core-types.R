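#' Point sets of detected object centroids
#'
#' A `point_set` is an ordered collection of 2D object centroids in pixel
#' coordinates. The convention throughout the package is x = column,
#' y = row, 0-based, with coordinates referring to pixel centers;
#' sub-pixel (continuous) centroids are allowed. Index `i` always refers
#' to the same object within one analysis run.
#'
#' @param x numeric vector of x coordinates (or an n x 2 matrix /
#'   data frame with columns `x`, `y`, in which case `y` is ignored).
#' @param y numeric vector of y coordinates.
#' @param channel_id optional integer channel label.
#' @param frame_index optional integer time-lapse frame index.
#' @return An object of class `point_set`: an n x 2 numeric matrix with
#'   columns `x`, `y` and attributes `channel_id`, `frame_index`.
#' @examples
#' P <- point_set(c(0, 3), c(0, 4))
#' n_points(P)
#' @export
point_set <- function(x, y = NULL, channel_id = NA_integer_,
                      frame_index = NA_integer_) {
  if (is.null(y)) {
    if (is.data.frame(x)) {
      stopifnot(all(c("x", "y") %in% names(x)))
      y <- x$y
      x <- x$x
    } else if (is.matrix(x)) {
      y <- x[, 2]
      x <- x[, 1]
    } else if (length(x) == 0) {
      y <- numeric(0)
    } else {
      stop("supply both x and y, or a two-column matrix / data frame")
    }
  }
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) && !all(is.finite(x) & is.finite(y)))
    stop("point coordinates must be finite")
  m <- cbind(x = x, y = y)
  structure(m,
            channel_id = as.integer(channel_id),
            frame_index = as.integer(frame_index),
            class = c("point_set", "matrix", "array"))
}

#' @rdname point_set
#' @param P a `point_set`.
#' @export
n_points <- function(P) nrow(P)

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set: %d points, channel %s, frame %s>\n",
              nrow(x), attr(x, "channel_id"), attr(x, "frame_index")))
  invisible(x)
}

#' Translations of the image plane
#'
#' The transformation class used by the matcher: rigid shifts
#' `p -> p + (dx, dy)`. Channel misalignment in two-channel acquisition
#' is well modeled by such a shift; rotation and scaling are not
#' expected between channels of the same field of view.
#'
#' @param dx,dy shift in pixels along x and y.
#' @return A `translation` object (named numeric vector of length 2).
#' @export
translation <- function(dx = 0, dy = 0) {
  v <- c(dx = as.numeric(dx), dy = as.numeric(dy))
  stopifnot(all(is.finite(v)))
  class(v) <- "translation"
  v
}

#' @rdname translation
#' @param t a `translation`.
#' @param norm norm tag, see [point_distance()].
#' @return `translation_magnitude`: the norm of the shift vector, pixels.
#' @export
translation_magnitude <- function(t, norm = "euclidean") {
  vec_norm(unclass(t), norm)
}

#' Apply a translation to a point set
#'
#' @param P a `point_set`.
#' @param t a `translation` (or numeric length-2 vector `c(dx, dy)`).
#' @return The shifted `point_set` (attributes preserved).
#' @export
translate_points <- function(P, t) {
  t <- as.numeric(t)
  out <- P
  out[, 1] <- P[, 1] + t[1]
  out[, 2] <- P[, 2] + t[2]
  out
}

# internal: vector norm under a norm tag
vec_norm <- function(v, norm = "euclidean") {
  switch(norm,
         euclidean = sqrt(sum(v^2)),
         manhattan = sum(abs(v)),
         maximum = max(abs(v), 0),
         stop(sprintf("unknown norm tag '%s'", norm)))
}

#' Distance between two points
#'
#' @param a,b numeric length-2 points `c(x, y)`.
#' @param norm one of `"euclidean"` (default), `"manhattan"`, `"maximum"`.
#' @return Non-negative scalar distance in pixels.
#' @examples
#' point_distance(c(0, 0), c(3, 4)) # 5
#' @export
point_distance <- function(a, b, norm = "euclidean") {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  vec_norm(a - b, norm)
}

# internal: all distances from each row of A (n x 2) to each row of B (m x 2);
# returns n x m matrix under the configured norm
cross_distances <- function(A, B, norm = "euclidean") {
  dx <- outer(A[, 1], B[, 1], "-")
  dy <- outer(A[, 2], B[, 2], "-")
  switch(norm,
         euclidean = sqrt(dx^2 + dy^2),
         manhattan = abs(dx) + abs(dy),
         maximum = pmax(abs(dx), abs(dy)),
         stop(sprintf("unknown norm tag '%s'", norm)))
}

#' Matcher parameters
#'
#' Container for the tunable parameters of the point-pattern matcher.
#'
#' @param delta matching distance in pixels (> 0): maximum allowed
#'   distance between a translated model point and its matched scene
#'   point. Default 4.
#' @param alpha matching ratio in `[0, 1]`: minimum fraction of
#'   `min(|P|, |Q|)` that must be paired for a matching to count as
#'   found. Default 0.1.
#' @param max_bias maximum allowed bias of a matching (dimensionless,
#'   >= 0). Default 0.2.
#' @param k maximum number of nearest neighbors considered per
#'   translated point (>= 1). Default 10.
#' @param max_translation maximum magnitude of the candidate translation
#'   in pixels. Default 3.
#' @param norm point-distance norm tag, see [point_distance()].
#' @return A list of class `ppm_params`.
#' @export
ppm_params <- function(delta = 4, alpha = 0.1, max_bias = 0.2, k = 10,
                       max_translation = 3, norm = "euclidean") {
  stopifnot(delta > 0, alpha >= 0, alpha <= 1, max_bias >= 0,
            k >= 1, max_translation >= 0)
  vec_norm(c(0, 0), norm) # validates the tag
  structure(list(delta = delta, alpha = alpha, max_bias = max_bias,
                 k = as.integer(k), max_translation = max_translation,
                 norm = norm),
            class = "ppm_params")
}

# internal constructor for matching results
new_matching <- function(pairs, translation, bias, accepted,
                         n_p = NA_integer_, n_q = NA_integer_) {
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  structure(list(pairs = pairs, translation = translation,
                 bias = bias, accepted = isTRUE(accepted),
                 n_p = as.integer(n_p), n_q = as.integer(n_q)),
            class = "ppm_matching")
}

empty_matching <- function(n_p = 0L, n_q = 0L) {
  new_matching(integer(0), translation(0, 0), NA_real_, FALSE, n_p, n_q)
}

#' @export
print.ppm_matching <- function(x, ...) {
  cat(sprintf(
    "<matching: %d pairs, t = (%.3f, %.3f), bias = %s, %s>\n",
    nrow(x$pairs), x$translation[1], x$translation[2],
    ifelse(is.na(x$bias), "NA", sprintf("%.4f", x$bias)),
    if (x$accepted) "accepted" else "not accepted"))
  invisible(x)
}

#' Validate a matching against its defining constraints
#'
#' Checks that a matching is one-to-one (no index of either point set
#' appears twice) and that every pair lies within the matching distance
#' under the matching's own translation. Used in tests and available to
#' users for post-hoc verification of results.
#'
#' @param M a `ppm_matching`.
#' @param P,Q the `point_set`s the matching refers to.
#' @param params the `ppm_params` in force.
#' @return `TRUE` invisibly; stops with an informative error otherwise.
#' @export
validate_matching <- function(M, P, Q, params = ppm_params()) {
  pr <- M$pairs
  if (nrow(pr) == 0) return(invisible(TRUE))
  if (anyDuplicated(pr[, 1]) || anyDuplicated(pr[, 2]))
    stop("matching is not one-to-one")
  if (any(pr[, 1] < 1 | pr[, 1] > nrow(P)) ||
      any(pr[, 2] < 1 | pr[, 2] > nrow(Q)))
    stop("matching indexes out of range")
  Pt <- translate_points(P, M$translation)
  d <- sqrt((Pt[pr[, 1], 1] - Q[pr[, 2], 1])^2 +
              (Pt[pr[, 1], 2] - Q[pr[, 2], 2])^2)
  if (params$norm != "euclidean") {
    d <- vapply(seq_len(nrow(pr)), function(r)
      point_distance(Pt[pr[r, 1], ], Q[pr[r, 2], ], params$norm), 0)
  }
  if (any(d > params$delta + 1e-9))
    stop("matched pair exceeds the matching distance")
  invisible(TRUE)
}

#' Read and write point sets as CSV
#'
#' Point sets are exchanged as CSV with a header containing at least
#' `x,y`; optional `frame` and `channel` columns are honored.
#'
#' @param path file path.
#' @param frame,channel optional filters applied on read when the file
#'   has the corresponding columns.
#' @return `read_point_csv`: a `point_set`.
#' @export
read_point_csv <- function(path, frame = NULL, channel = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x", "y") %in% names(df)))
  if (!is.null(frame) && "frame" %in% names(df))
    df <- df[df$frame == frame, , drop = FALSE]
  if (!is.null(channel) && "channel" %in% names(df))
    df <- df[df$channel == channel, , drop = FALSE]
  point_set(df$x, df$y,
            channel_id = if ("channel" %in% names(df) && nrow(df))
              df$channel[1] else NA_integer_,
            frame_index = if ("frame" %in% names(df) && nrow(df))
              df$frame[1] else NA_integer_)
}

#' @rdname read_point_csv
#' @param P a `point_set` to write.
#' @export
write_point_csv <- function(P, path) {
  df <- data.frame(x = P[, 1], y = P[, 2])
  ch <- attr(P, "channel_id"); fr <- attr(P, "frame_index")
  if (!is.na(ch)) df$channel <- ch
  if (!is.na(fr)) df$frame <- fr
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
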