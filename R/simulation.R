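#' Preset association scenarios
#'
#' The three association levels used by the controlled simulation
#' experiments: high (0.7477 / 0.8557 for channels 1 / 2), intermediate
#' (0.5225 / 0.4715) and low (0.2072 / 0.2805).
#'
#' @return Named list of length-2 numeric vectors
#'   `c(assoc_ch1, assoc_ch2)`.
#' @export
scenario_presets <- function() {
  list(high = c(assoc_ch1 = 0.7477, assoc_ch2 = 0.8557),
       intermediate = c(assoc_ch1 = 0.5225, assoc_ch2 = 0.4715),
       low = c(assoc_ch1 = 0.2072, assoc_ch2 = 0.2805))
}

#' Integer object counts realizing preset association levels
#'
#' Association is controlled by adding and removing objects so that the
#' preset levels are obtained exactly: with `m` shared objects and
#' channel totals `n_ch1`, `n_ch2`, the ground-truth associations are
#' `m / n_ch1` and `m / n_ch2`. This searches for integers reproducing
#' both targets to 4 decimal places, anchoring one channel total at
#' `n_base` (or as close to it as possible).
#'
#' @param assoc_ch1,assoc_ch2 target association fractions in `(0, 1]`,
#'   given to 4 decimals.
#' @param n_base baseline number of objects per channel (default 111).
#' @param window how far from `n_base` the channel totals may stray.
#' @return A list with `m_shared`, `n_ch1`, `n_ch2`, `achieved_ch1`,
#'   `achieved_ch2` (the exact fractions). Errors if no integer
#'   solution exists within the window, reporting the nearest
#'   achievable fractions.
#' @examples
#' solve_counts(0.7477, 0.8557) # 83 shared of 111 / 97
#' @export
solve_counts <- function(assoc_ch1, assoc_ch2, n_base = 111, window = 60) {
  stopifnot(assoc_ch1 > 0, assoc_ch1 <= 1, assoc_ch2 > 0, assoc_ch2 <= 1)
  a1 <- round(assoc_ch1, 4); a2 <- round(assoc_ch2, 4)
  offs <- seq(-window, window)
  n1_cands <- n_base + offs[order(abs(offs))]
  best_gap <- Inf; best <- NULL
  for (n1 in n1_cands) {
    if (n1 < 1) next
    m_cands <- which(round(seq_len(n1) / n1, 4) == a1)
    for (m in m_cands) {
      n2_lo <- max(m, n_base - window); n2_hi <- n_base + window
      if (n2_lo > n2_hi) next
      n2s <- n2_lo:n2_hi
      ok <- n2s[round(m / n2s, 4) == a2]
      if (length(ok)) {
        n2 <- ok[which.min(abs(ok - n_base))]
        return(list(m_shared = m, n_ch1 = n1, n_ch2 = n2,
                    achieved_ch1 = m / n1, achieved_ch2 = m / n2))
      }
      # track nearest achievable for the error message
      n2_best <- n2s[which.min(abs(round(m / n2s, 4) - a2))]
      gap <- abs(round(m / n2_best, 4) - a2)
      if (gap < best_gap) {
        best_gap <- gap
        best <- c(m / n1, m / n2_best)
      }
    }
  }
  stop(sprintf(
    "no integer solution for targets (%.4f, %.4f) near n_base = %d; nearest achievable: (%.4f, %.4f)",
    a1, a2, n_base,
    if (is.null(best)) NA else best[1], if (is.null(best)) NA else best[2]))
}

#' Simulation parameters
#'
#' Parameters of a simulated two-channel field of view: spots with
#' varying peak intensity on a flat background with additive Gaussian
#' noise, a global translation of channel 2 in a random direction, and
#' independent per-object Gaussian jitter emulating object movement
#' between the two acquisitions.
#'
#' @param n_base baseline objects per channel (default 111).
#' @param assoc_ch1,assoc_ch2 target association fractions.
#' @param shift_magnitude global channel shift magnitude L in pixels
#'   (direction drawn uniformly at random).
#' @param jitter_sigma per-object, per-axis movement s.d. in pixels.
#' @param image_size `c(H, W)` in pixels.
#' @param spot_sigma Gaussian spot profile s.d. in pixels.
#' @param intensity_range `c(min, max)` peak intensities (arbitrary
#'   detector units).
#' @param background_level flat background offset added before noise.
#' @param background_noise_sigma s.d. of the additive Gaussian noise.
#' @param min_separation minimum distance between ground-truth object
#'   centers within a channel, keeping detections identifiable.
#' @param seed integer RNG seed (`NA` = use current RNG state).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_base = 111,
                       assoc_ch1 = 0.7477, assoc_ch2 = 0.8557,
                       shift_magnitude = 0, jitter_sigma = 0,
                       image_size = c(256, 256), spot_sigma = 1.5,
                       intensity_range = c(200, 1000),
                       background_level = 100,
                       background_noise_sigma = 20,
                       min_separation = 4, seed = NA_integer_) {
  stopifnot(assoc_ch1 > 0, assoc_ch1 <= 1, assoc_ch2 > 0, assoc_ch2 <= 1,
            shift_magnitude >= 0, jitter_sigma >= 0,
            length(image_size) == 2, spot_sigma > 0,
            background_noise_sigma >= 0, min_separation >= 0)
  structure(as.list(environment()), class = "sim_params")
}

# internal: rejection-sample n points in the image interior with a
# minimum separation from each other and from `avoid`
place_points <- function(n, image_size, min_separation, margin = 8,
                         avoid = NULL, max_tries = 20000L) {
  H <- image_size[1]; W <- image_size[2]
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  if ((W - 2 * margin) * (H - 2 * margin) < n * max(min_separation, 1)^2)
    stop("image too small for requested object count at minimum separation")
  pts <- matrix(NA_real_, n, 2)
  have <- 0L
  tries <- 0L
  while (have < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("image too small for requested object count at minimum separation")
    cand <- c(stats::runif(1, margin, W - 1 - margin),
              stats::runif(1, margin, H - 1 - margin))
    ok <- TRUE
    if (have > 0) {
      d2 <- (pts[seq_len(have), 1] - cand[1])^2 +
        (pts[seq_len(have), 2] - cand[2])^2
      ok <- all(d2 >= min_separation^2)
    }
    if (ok && !is.null(avoid) && nrow(avoid) > 0) {
      d2 <- (avoid[, 1] - cand[1])^2 + (avoid[, 2] - cand[2])^2
      ok <- all(d2 >= min_separation^2)
    }
    if (ok) {
      have <- have + 1L
      pts[have, ] <- cand
    }
  }
  colnames(pts) <- c("x", "y")
  pts
}

# internal: render Gaussian spots onto an H x W image
render_spot_image <- function(points, peaks, image_size, spot_sigma,
                              background_level, background_noise_sigma) {
  H <- image_size[1]; W <- image_size[2]
  img <- matrix(0, H, W)
  r_win <- ceiling(4 * spot_sigma)
  for (s in seq_len(nrow(points))) {
    x0 <- points[s, 1]; y0 <- points[s, 2]
    cc <- max(1, floor(x0 + 1 - r_win)):min(W, ceiling(x0 + 1 + r_win))
    rr <- max(1, floor(y0 + 1 - r_win)):min(H, ceiling(y0 + 1 + r_win))
    gx <- exp(-((cc - 1 - x0)^2) / (2 * spot_sigma^2))
    gy <- exp(-((rr - 1 - y0)^2) / (2 * spot_sigma^2))
    img[rr, cc] <- img[rr, cc] + peaks[s] * outer(gy, gx)
  }
  img <- img + background_level
  if (background_noise_sigma > 0)
    img <- img + matrix(stats::rnorm(H * W, 0, background_noise_sigma), H, W)
  pmax(round(img), 0)
}

#' Generate one synthetic two-channel scene
#'
#' Places shared and channel-unique objects with exact preset
#' association counts (see [solve_counts()]), applies the global shift
#' `L (cos t, sin t)` with a random direction and independent per-axis
#' Gaussian jitter to the channel-2 copies of the shared objects, and
#' (optionally) renders both channels as spot images with additive
#' background noise. The full ground-truth correspondence is returned.
#'
#' @param params a [sim_params()] object.
#' @param render if `FALSE`, skip image rendering (ground-truth
#'   coordinates only); much faster for matcher-level experiments.
#' @return A list of class `synthetic_scene`: `ch1`, `ch2`
#'   (`point_set`s, shared objects first), `gt_shared`,
#'   `gt_unique_ch1`, `gt_unique_ch2`, `true_pairs` (m x 2 integer
#'   matrix of indices into `ch1` / `ch2`), `applied_shift`
#'   (`translation`), `counts`, `images` (list of two matrices or
#'   `NULL`), `params`.
#' @export
generate_scene <- function(params = sim_params(), render = TRUE) {
  if (!is.na(params$seed)) set.seed(params$seed)
  cnt <- solve_counts(params$assoc_ch1, params$assoc_ch2, params$n_base)
  m <- cnt$m_shared
  u1 <- cnt$n_ch1 - m
  u2 <- cnt$n_ch2 - m

  ch1_pts <- place_points(cnt$n_ch1, params$image_size,
                          params$min_separation)
  shared <- ch1_pts[seq_len(m), , drop = FALSE]

  theta <- stats::runif(1, 0, 2 * pi)
  shift <- c(params$shift_magnitude * cos(theta),
             params$shift_magnitude * sin(theta))
  jit <- matrix(stats::rnorm(2 * m, 0, params$jitter_sigma), m, 2)
  ch2_shared <- sweep(shared, 2, -shift) + jit
  ch2_unique <- place_points(u2, params$image_size, params$min_separation,
                             avoid = ch2_shared)
  ch2_pts <- rbind(ch2_shared, ch2_unique)

  images <- NULL
  if (render) {
    peaks1 <- stats::runif(cnt$n_ch1, params$intensity_range[1],
                           params$intensity_range[2])
    peaks2 <- stats::runif(cnt$n_ch2, params$intensity_range[1],
                           params$intensity_range[2])
    images <- list(
      ch1 = render_spot_image(ch1_pts, peaks1, params$image_size,
                              params$spot_sigma, params$background_level,
                              params$background_noise_sigma),
      ch2 = render_spot_image(ch2_pts, peaks2, params$image_size,
                              params$spot_sigma, params$background_level,
                              params$background_noise_sigma))
  }

  structure(list(
    ch1 = point_set(ch1_pts, channel_id = 1L),
    ch2 = point_set(ch2_pts, channel_id = 2L),
    gt_shared = point_set(shared, channel_id = 1L),
    gt_unique_ch1 = point_set(ch1_pts[seq_len(u1) + m, , drop = FALSE],
                              channel_id = 1L),
    gt_unique_ch2 = point_set(ch2_unique, channel_id = 2L),
    true_pairs = cbind(i = seq_len(m), j = seq_len(m)),
    applied_shift = translation(shift[1], shift[2]),
    counts = cnt,
    images = images,
    params = params
  ), class = "synthetic_scene")
}

#' Build the full factorial simulation grid
#'
#' Crosses association scenarios, global shift magnitudes, jitter
#' levels and replicates into a list of scene manifests. Each manifest
#' carries its own derived seed, so any scene can be realized
#' independently and reproducibly with [realize_scene()]. The default
#' grid is 4 shifts x 6 jitter levels = 24 parameter combinations x 3
#' scenarios x 10 replicates = 720 scenes.
#'
#' @param scenarios character vector naming entries of
#'   [scenario_presets()], or a named list of `c(assoc_ch1, assoc_ch2)`
#'   vectors.
#' @param shifts global shift magnitudes in pixels.
#' @param sigmas per-object jitter standard deviations in pixels.
#' @param replicates replicates per parameter combination.
#' @param seed base seed; per-scene seeds are derived from it.
#' @param ... further arguments passed to [sim_params()] (image size,
#'   spot rendering, ...).
#' @return A list of class `sim_grid` of scene manifests (each a list
#'   with `scenario`, `shift`, `sigma`, `replicate`, `seed`, `params`).
#' @export
generate_grid <- function(scenarios = names(scenario_presets()),
                          shifts = 0:3,
                          sigmas = c(0, 0.5, 1, 1.5, 2, 2.5),
                          replicates = 10, seed = 1, ...) {
  presets <- scenario_presets()
  if (is.character(scenarios)) {
    stopifnot(all(scenarios %in% names(presets)))
    scen_list <- presets[scenarios]
  } else {
    scen_list <- scenarios
  }
  design <- expand.grid(replicate = seq_len(replicates),
                        sigma = sigmas, shift = shifts,
                        scenario = names(scen_list),
                        stringsAsFactors = FALSE)
  out <- vector("list", nrow(design))
  for (r in seq_len(nrow(design))) {
    sc <- design$scenario[r]
    scene_seed <- (seed + 104729 * r) %% 2147483647L
    out[[r]] <- structure(list(
      scenario = sc,
      shift = design$shift[r],
      sigma = design$sigma[r],
      replicate = design$replicate[r],
      seed = scene_seed,
      params = sim_params(assoc_ch1 = scen_list[[sc]][1],
                          assoc_ch2 = scen_list[[sc]][2],
                          shift_magnitude = design$shift[r],
                          jitter_sigma = design$sigma[r],
                          seed = scene_seed, ...)
    ), class = "scene_manifest")
  }
  structure(out, class = c("sim_grid", "list"))
}

#' @rdname generate_grid
#' @param manifest a `scene_manifest` from [generate_grid()].
#' @param render render images (see [generate_scene()]).
#' @return `realize_scene`: a `synthetic_scene`.
#' @export
realize_scene <- function(manifest, render = FALSE) {
  generate_scene(manifest$params, render = render)
}

#' Simulate a two-channel time-lapse of moving objects
#'
#' Fully associated objects performing independent Gaussian random
#' walks, imaged by both channels at every frame. When the delay driver
#' pairs channel 1 at frame `t` with channel 2 at frame `t + n`, the
#' apparent displacement of each object grows with `n` as the random
#' walk diffuses — emulating the imaging-delay experiment.
#'
#' @param n_objects number of objects.
#' @param n_frames number of frames.
#' @param step_sigma per-axis random-walk step s.d. per frame (pixels).
#' @param image_size,spot_sigma,intensity_range,background_level,background_noise_sigma,min_separation
#'   as in [sim_params()].
#' @param render render image stacks (otherwise coordinates only).
#' @param seed RNG seed.
#' @return A list of class `synthetic_timelapse`: `tracks` (list of
#'   n_objects x 2 coordinate matrices, one per frame), `stack1`,
#'   `stack2` (H x W x n_frames arrays or `NULL`).
#' @export
simulate_timelapse <- function(n_objects = 40, n_frames = 12,
                               step_sigma = 1, image_size = c(128, 128),
                               spot_sigma = 1.5,
                               intensity_range = c(200, 1000),
                               background_level = 100,
                               background_noise_sigma = 20,
                               min_separation = 6,
                               render = TRUE, seed = NA_integer_) {
  if (!is.na(seed)) set.seed(seed)
  margin <- 8 + ceiling(step_sigma * sqrt(n_frames) * 3)
  pos <- place_points(n_objects, image_size, min_separation,
                      margin = margin)
  tracks <- vector("list", n_frames)
  tracks[[1]] <- pos
  for (f in seq_len(n_frames - 1) + 1) {
    pos <- pos + matrix(stats::rnorm(2 * n_objects, 0, step_sigma),
                        n_objects, 2)
    tracks[[f]] <- pos
  }
  stack1 <- stack2 <- NULL
  if (render) {
    H <- image_size[1]; W <- image_size[2]
    stack1 <- array(0, c(H, W, n_frames))
    stack2 <- array(0, c(H, W, n_frames))
    peaks <- stats::runif(n_objects, intensity_range[1], intensity_range[2])
    for (f in seq_len(n_frames)) {
      stack1[, , f] <- render_spot_image(tracks[[f]], peaks, image_size,
                                         spot_sigma, background_level,
                                         background_noise_sigma)
      stack2[, , f] <- render_spot_image(tracks[[f]], peaks, image_size,
                                         spot_sigma, background_level,
                                         background_noise_sigma)
    }
  }
  structure(list(tracks = tracks, stack1 = stack1, stack2 = stack2,
                 n_frames = n_frames, image_size = image_size),
            class = "synthetic_timelapse")
}

#' Write a scene to disk
#'
#' Writes the two rendered channels as a 2-page TIFF, the ground truth
#' as CSV (`x,y,channel,shared_id`) and a JSON manifest of parameters
#' and counts.
#'
#' @param scene a `synthetic_scene` (rendered).
#' @param tiff_path,csv_path,json_path output paths (any may be `NULL`).
#' @return `scene`, invisibly.
#' @export
write_scene <- function(scene, tiff_path = NULL, csv_path = NULL,
                        json_path = NULL) {
  if (!is.null(tiff_path)) {
    stopifnot(!is.null(scene$images))
    # 16-bit, scaled so integer ADU values survive the round trip
    tiff::writeTIFF(lapply(scene$images, function(im) im / 65535),
                    tiff_path, bits.per.sample = 16)
  }
  if (!is.null(csv_path)) {
    m <- nrow(scene$true_pairs)
    df <- rbind(
      data.frame(x = scene$ch1[, 1], y = scene$ch1[, 2], channel = 1L,
                 shared_id = c(seq_len(m),
                               rep(NA_integer_, nrow(scene$ch1) - m))),
      data.frame(x = scene$ch2[, 1], y = scene$ch2[, 2], channel = 2L,
                 shared_id = c(seq_len(m),
                               rep(NA_integer_, nrow(scene$ch2) - m))))
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    p <- scene$params
    jsonlite::write_json(list(
      counts = scene$counts,
      applied_shift = as.numeric(scene$applied_shift),
      params = p[setdiff(names(p), "image_size")],
      image_size = p$image_size
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(scene)
}
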