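#' Assign detected points to ground-truth objects
#'
#' Greedy one-to-one assignment of detections to the nearest
#' ground-truth object within a gating radius; detections with no
#' ground-truth object in range remain unassigned (spurious).
#'
#' @param detected,gt `point_set`s (detections and ground truth).
#' @param radius gating radius in pixels (default 2).
#' @return Integer vector, one entry per detection: the ground-truth
#'   index, or `NA` if unassigned.
#' @export
assign_detections <- function(detected, gt, radius = 2) {
  n <- nrow(detected)
  out <- rep(NA_integer_, n)
  if (n == 0 || nrow(gt) == 0) return(out)
  D <- cross_distances(detected, gt)
  cand <- which(D <= radius, arr.ind = TRUE)
  if (nrow(cand) == 0) return(out)
  cand <- cand[order(D[cand]), , drop = FALSE]
  used_gt <- logical(nrow(gt))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (is.na(out[i]) && !used_gt[j]) {
      out[i] <- j
      used_gt[j] <- TRUE
    }
  }
  out
}

#' Score a matching against ground-truth correspondence
#'
#' Counts true positives (object paired with its correct counterpart),
#' false positives (object paired with a wrong counterpart, or a pair
#' involving a spurious detection) and false negatives (objects not
#' paired although a counterpart exists among the detections), then
#' derives precision, recall and the F-measure. When no pairing is
#' correct and the counts leave a rate undefined, the corresponding
#' value is `NA` rather than 0, so failed matchings appear as missing
#' values in summaries.
#'
#' @param M a `ppm_matching` (pairs index the detected sets).
#' @param true_pairs integer matrix of ground-truth correspondences
#'   (columns: ground-truth index in channel 1, in channel 2).
#' @param map1,map2 integer vectors mapping detected indices to
#'   ground-truth indices (`NA` = spurious detection); defaults assume
#'   detections are the ground-truth points themselves.
#' @return A list of class `match_score`: `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f_measure`.
#' @export
score_matching <- function(M, true_pairs, map1 = NULL, map2 = NULL) {
  pairs <- M$pairs
  if (is.null(map1)) map1 <- seq_len(max(c(M$n_p, pairs[, 1], 0)))
  if (is.null(map2)) map2 <- seq_len(max(c(M$n_q, pairs[, 2], 0)))
  true_pairs <- matrix(as.integer(true_pairs), ncol = 2)

  true_key <- paste(true_pairs[, 1], true_pairs[, 2])
  tp <- 0L; fp <- 0L
  if (nrow(pairs) > 0) {
    g1 <- map1[pairs[, 1]]
    g2 <- map2[pairs[, 2]]
    correct <- !is.na(g1) & !is.na(g2) & paste(g1, g2) %in% true_key
    tp <- sum(correct)
    fp <- nrow(pairs) - tp
  }
  # counterparts exist: both ground-truth endpoints were actually detected
  present1 <- true_pairs[, 1] %in% map1[!is.na(map1)]
  present2 <- true_pairs[, 2] %in% map2[!is.na(map2)]
  fn <- sum(present1 & present2) - tp

  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(tp = tp, fp = fp, fn = as.integer(fn),
                 precision = precision, recall = recall, f_measure = f),
            class = "match_score")
}

#' Run the simulation benchmark (PPM vs ICP)
#'
#' For every scene of a simulation grid: obtain the two point sets
#' (ground-truth coordinates, or detections from the rendered images),
#' run both the point-pattern matcher and the ICP baseline, and score
#' each against the ground-truth correspondence. Results come back as
#' a tidy table, one row per scene and method.
#'
#' @param grid a `sim_grid` from [generate_grid()].
#' @param ppm a [ppm_params()] object.
#' @param icp an [icp_params()] object.
#' @param use_detection detect spots from rendered images instead of
#'   using ground-truth coordinates.
#' @param det a [detection_params()] object (when `use_detection`).
#' @param gating_radius detection-to-ground-truth gating radius,
#'   pixels.
#' @param verbose emit one structured log line per scene and method.
#' @return A data frame with columns `scenario`, `shift`, `sigma`,
#'   `replicate`, `method`, `n_pairs`, `bias`, `tx`, `ty`, `accepted`,
#'   `tp`, `fp`, `fn`, `precision`, `recall`, `f_measure`, `failed`.
#' @export
run_benchmark <- function(grid, ppm = ppm_params(), icp = icp_params(),
                          use_detection = FALSE,
                          det = detection_params(),
                          gating_radius = 2, verbose = FALSE) {
  rows <- vector("list", 2 * length(grid))
  ri <- 0L
  for (mf in grid) {
    scene <- tryCatch(realize_scene(mf, render = use_detection),
                      error = function(e) e)
    if (inherits(scene, "error")) {
      warning(sprintf("scene %s/L=%s/s=%s/rep=%d failed: %s",
                      mf$scenario, mf$shift, mf$sigma, mf$replicate,
                      conditionMessage(scene)))
      next
    }
    if (use_detection) {
      d1 <- detect_spots(scene$images$ch1, det)
      d2 <- detect_spots(scene$images$ch2, det)
      P <- d1$centroids; Q <- d2$centroids
      map1 <- assign_detections(P, scene$ch1, gating_radius)
      map2 <- assign_detections(Q, scene$ch2, gating_radius)
    } else {
      P <- scene$ch1; Q <- scene$ch2
      map1 <- map2 <- NULL
    }
    results <- list(
      ppm = ppm_match(P, Q, ppm),
      icp = tryCatch(icp_register(P, Q, icp), error = function(e) NULL))
    for (method in names(results)) {
      M <- results[[method]]
      if (is.null(M)) next
      sc <- score_matching(M, scene$true_pairs, map1, map2)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        scenario = mf$scenario, shift = mf$shift, sigma = mf$sigma,
        replicate = mf$replicate, method = method,
        n_pairs = nrow(M$pairs), bias = M$bias,
        tx = M$translation[1], ty = M$translation[2],
        accepted = M$accepted,
        tp = sc$tp, fp = sc$fp, fn = sc$fn,
        precision = sc$precision, recall = sc$recall,
        f_measure = sc$f_measure,
        failed = sc$tp == 0L)
      if (verbose)
        message(sprintf(
          "scene=%s/L=%s/s=%s/rep=%d method=%s |M|=%d bias=%.3f t=(%.2f,%.2f) F=%.3f",
          mf$scenario, mf$shift, mf$sigma, mf$replicate, method,
          nrow(M$pairs), ifelse(is.na(M$bias), NaN, M$bias),
          M$translation[1], M$translation[2],
          ifelse(is.na(sc$f_measure), NaN, sc$f_measure)))
    }
  }
  do.call(rbind, rows[seq_len(ri)])
}

#' Summarize a benchmark table
#'
#' Mean F-measure (missing values dropped) and failure counts per
#' scenario, parameter combination and method.
#'
#' @param results a table from [run_benchmark()].
#' @return Aggregated data frame.
#' @export
summarize_benchmark <- function(results) {
  agg <- stats::aggregate(
    cbind(f_measure, failed) ~ scenario + shift + sigma + method,
    data = results, FUN = function(v) mean(v, na.rm = TRUE),
    na.action = stats::na.pass)
  names(agg)[names(agg) == "f_measure"] <- "mean_f"
  names(agg)[names(agg) == "failed"] <- "failure_rate"
  agg
}

#' Plot benchmark summaries
#'
#' Mean F-measure against jitter (faceted by shift) for each method and
#' scenario. Requires ggplot2.
#'
#' @param results a table from [run_benchmark()].
#' @return A ggplot object.
#' @export
plot_benchmark <- function(results) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_benchmark requires ggplot2")
  agg <- summarize_benchmark(results)
  ggplot2::ggplot(agg, ggplot2::aes(
    x = sigma, y = mean_f, color = scenario, shape = method,
    linetype = method, group = interaction(scenario, method))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~shift, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "object movement sd (px)", y = "mean F-measure") +
    ggplot2::ylim(0, 1)
}

#' Imaging-delay robustness experiment
#'
#' Pairs channel 1 at frame `t` with channel 2 at frame `t + n` for a
#' range of delays `n`, computes the point-pattern association (for one
#' or more matching distances) and the objectwise-overlap baseline for
#' every valid `t`, and averages over frames. Estimates are also
#' reported relative to the non-delayed (`n = 0`) value, which is 1 by
#' construction.
#'
#' @param stack1,stack2 H x W x T numeric arrays (the two channels'
#'   time-lapse stacks), equal frame counts.
#' @param delays integer frame offsets (must include 0 for the relative
#'   normalization; maximum below the frame count).
#' @param ppm_deltas matching distances to evaluate, pixels.
#' @param ppm base [ppm_params()] whose `delta` is swept.
#' @param det a [detection_params()] object used on every frame.
#' @return A list of class `delay_result`: `table` (data frame with
#'   `delay`, `method`, `estimate`, `relative`), `detections` (per
#'   channel, per frame).
#' @export
run_delay_experiment <- function(stack1, stack2, delays = 0:4,
                                 ppm_deltas = c(4, 6, 8, 10),
                                 ppm = ppm_params(),
                                 det = detection_params(min_size = 8)) {
  stopifnot(length(dim(stack1)) == 3, all(dim(stack1) == dim(stack2)))
  n_frames <- dim(stack1)[3]
  delays <- sort(unique(as.integer(delays)))
  if (max(delays) >= n_frames) stop("delay must be below the frame count")
  if (delays[1] != 0L) stop("delays must include 0 for normalization")

  det1 <- lapply(seq_len(n_frames), function(f)
    detect_spots(stack1[, , f], det))
  det2 <- lapply(seq_len(n_frames), function(f)
    detect_spots(stack2[, , f], det))

  methods <- c(sprintf("ppm_delta%g", ppm_deltas), "object_overlap")
  est <- matrix(NA_real_, length(delays), length(methods),
                dimnames = list(NULL, methods))
  for (di in seq_along(delays)) {
    n <- delays[di]
    ts <- seq_len(n_frames - n)
    vals <- matrix(NA_real_, length(ts), length(methods))
    for (ti in seq_along(ts)) {
      a <- det1[[ts[ti]]]
      b <- det2[[ts[ti] + n]]
      for (mi in seq_along(ppm_deltas)) {
        p <- ppm
        p$delta <- ppm_deltas[mi]
        vals[ti, mi] <- association(a$centroids, b$centroids, p)$assoc_ch1
      }
      vals[ti, length(methods)] <-
        unname(object_overlap(a$labels, b$labels)[1])
    }
    est[di, ] <- colMeans(vals)
  }
  tab <- data.frame(
    delay = rep(delays, times = length(methods)),
    method = rep(methods, each = length(delays)),
    estimate = as.numeric(est))
  base <- est[1, ]
  tab$relative <- as.numeric(sweep(est, 2, base, "/"))
  structure(list(table = tab, detections = list(ch1 = det1, ch2 = det2)),
            class = "delay_result")
}
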