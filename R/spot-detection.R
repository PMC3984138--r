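#' Spot detection parameters
#'
#' @param dog_sigma_small,dog_sigma_large standard deviations in pixels
#'   of the two Gaussian blurs whose difference forms the band-pass
#'   response; `dog_sigma_small < dog_sigma_large`. Defaults 1 and 2 px,
#'   typical for diffraction-limited spots.
#' @param threshold either the string `"otsu"` (Otsu's threshold on the
#'   band-pass response, the default) or a numeric manual threshold on
#'   the response.
#' @param min_size minimum component area in pixels; smaller particles
#'   are removed so that noise and small debris are not detected as
#'   spots. Use 3 for fixed-cell images and 8 for noisier live-cell
#'   images.
#' @param split_touching separate touching spots by watershed splitting
#'   of the band-pass response within the mask (default `TRUE`);
#'   without it, spots closer than a few widths merge into one
#'   component.
#' @param watershed_tolerance minimum response-height difference
#'   between two local maxima for them to count as separate objects
#'   (response units), passed to the watershed transform.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(dog_sigma_small = 1, dog_sigma_large = 2,
                             threshold = "otsu", min_size = 3,
                             split_touching = TRUE,
                             watershed_tolerance = 10) {
  if (dog_sigma_small >= dog_sigma_large)
    stop("dog_sigma_small must be smaller than dog_sigma_large")
  stopifnot(min_size >= 1, watershed_tolerance >= 0)
  if (!identical(threshold, "otsu") && !is.numeric(threshold))
    stop("threshold must be \"otsu\" or a numeric value")
  structure(list(dog_sigma_small = dog_sigma_small,
                 dog_sigma_large = dog_sigma_large,
                 threshold = threshold,
                 min_size = as.integer(min_size),
                 split_touching = isTRUE(split_touching),
                 watershed_tolerance = watershed_tolerance),
            class = "detection_params")
}

#' Subtract the modal background intensity
#'
#' Removes the flat background by subtracting the most common intensity
#' value of the image (the mode of the integer intensity histogram) and
#' clipping at zero. In fluorescence images the background dominates
#' the histogram, so its mode is a robust background estimate.
#'
#' @param image 2D numeric matrix of intensities (matrix rows are image
#'   rows; finite values required).
#' @return Matrix of the same shape, `pmax(image - mode, 0)`.
#' @export
subtract_background_mode <- function(image) {
  stopifnot(is.matrix(image), length(image) > 0)
  if (!all(is.finite(image))) stop("image contains non-finite pixels")
  v <- as.integer(round(image))
  shift <- min(v)
  counts <- tabulate(v - shift + 1L)
  mode_val <- which.max(counts) + shift - 1L   # ties -> smallest value
  pmax(image - mode_val, 0)
}

#' Difference-of-Gaussians band-pass filter
#'
#' Enhances resolution-limited spots: the image is blurred with two
#' Gaussians and the wider blur subtracted from the narrower, leaving a
#' band-pass response that peaks at spot centers and suppresses both
#' pixel noise and smooth background.
#'
#' @param image 2D numeric matrix.
#' @param dog_sigma_small,dog_sigma_large Gaussian standard deviations
#'   in pixels; the small one must be smaller.
#' @return Matrix of the band-pass response (same shape as input).
#' @export
dog_filter <- function(image, dog_sigma_small = 1, dog_sigma_large = 2) {
  if (dog_sigma_small >= dog_sigma_large)
    stop("dog_sigma_small must be smaller than dog_sigma_large")
  stopifnot(is.matrix(image))
  g1 <- EBImage::gblur(image, sigma = dog_sigma_small)
  g2 <- EBImage::gblur(image, sigma = dog_sigma_large)
  as.matrix(g1 - g2)
}

#' 8-connected component labeling
#'
#' Labels connected foreground regions of a binary mask using
#' 8-connectivity (diagonal neighbors connect), the 2D standard for
#' particle masks. Labels are assigned in raster order of each
#' component's first pixel, starting at 1.
#'
#' @param mask logical or 0/1 matrix.
#' @return Integer matrix of the same shape; 0 = background.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  fg <- which(mask)
  if (length(fg) == 0) return(lab)

  parent <- seq_along(fg)
  pos <- integer(H * W)          # linear index -> rank in fg
  pos[fg] <- seq_along(fg)

  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }

  r <- ((fg - 1L) %% H) + 1L
  c <- ((fg - 1L) %/% H) + 1L
  # neighbor offsets covering all 8-adjacencies once: E, S, SE, NE
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
  for (o in offs) {
    rr <- r + o[1]; cc <- c + o[2]
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    nb <- (cc[ok] - 1L) * H + rr[ok]
    hit <- which(ok)[mask[nb]]
    nbr <- pos[(c[hit] + o[2] - 1L) * H + (r[hit] + o[1])]
    for (q in seq_along(hit)) union_(hit[q], nbr[q])
  }

  roots <- vapply(seq_along(fg), find, 0L)
  ids <- match(roots, unique(roots))   # fg is raster-ordered already
  lab[fg] <- ids
  lab
}

#' Detect fluorescent spots in a single-channel image
#'
#' The full detection recipe: modal background subtraction, a
#' difference-of-Gaussians band-pass, thresholding of the response
#' (Otsu by default, manual override available), component labeling —
#' watershed splitting of the response by default so that touching
#' spots separate, plain 8-connected labeling otherwise — removal of
#' components smaller than `min_size` pixels, and unweighted area
#' centroids of the surviving components.
#'
#' @param image 2D numeric matrix (grayscale intensities).
#' @param params a [detection_params()] object.
#' @return A list of class `detection_result`: `mask` (logical matrix),
#'   `labels` (integer matrix), `centroids` (a `point_set`, x = column,
#'   y = row, 0-based pixel centers, ordered by label), `object_areas`
#'   (integer vector), `threshold` (the numeric threshold applied).
#' @export
detect_spots <- function(image, params = detection_params()) {
  stopifnot(is.matrix(image))
  bg <- subtract_background_mode(image)
  resp <- dog_filter(bg, params$dog_sigma_small, params$dog_sigma_large)

  thr <- params$threshold
  if (identical(thr, "otsu")) {
    rng <- range(resp)
    if (diff(rng) == 0) {
      thr <- Inf          # flat response: nothing to detect
    } else {
      thr <- EBImage::otsu(EBImage::Image(resp), range = rng, levels = 256)
    }
  }
  mask <- resp > thr
  if (params$split_touching && any(mask)) {
    lab <- EBImage::imageData(EBImage::watershed(
      EBImage::Image(resp * mask), tolerance = params$watershed_tolerance,
      ext = 1))
    lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  } else {
    lab <- label_components(mask)
  }

  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas >= params$min_size)
    relab <- integer(length(areas))
    relab[keep] <- seq_along(keep)
    lab[lab > 0] <- relab[lab[lab > 0]]
    mask <- lab > 0
    areas <- areas[keep]
  } else {
    areas <- integer(0)
  }

  if (length(areas) > 0) {
    idx <- which(lab > 0)
    rr <- ((idx - 1L) %% nrow(lab)) + 1L
    cc <- ((idx - 1L) %/% nrow(lab)) + 1L
    g <- lab[idx]
    cx <- tapply(cc, g, mean) - 1   # x = column, 0-based pixel centers
    cy <- tapply(rr, g, mean) - 1   # y = row
    centroids <- point_set(as.numeric(cx), as.numeric(cy))
  } else {
    centroids <- point_set(numeric(0), numeric(0))
  }

  structure(list(mask = mask, labels = lab, centroids = centroids,
                 object_areas = as.integer(areas), threshold = thr),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection: %d objects, threshold %.4g>\n",
              length(x$object_areas), x$threshold))
  invisible(x)
}

#' Read a channel from a grayscale TIFF
#'
#' @param path TIFF file path (single frame or multi-page stack).
#' @param frame 1-based page index for stacks.
#' @return Numeric matrix of intensities as stored (no rescaling).
#' @export
read_channel_tiff <- function(path, frame = 1L) {
  img <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (frame > length(img)) stop("frame index beyond stack length")
  m <- img[[frame]]
  if (length(dim(m)) == 3) m <- m[, , 1]
  m
}

#' Write a detection result to disk
#'
#' Writes the binary mask as TIFF and the centroids as CSV with columns
#' `x,y,area`.
#'
#' @param det a `detection_result`.
#' @param mask_path,csv_path output file paths (either may be `NULL` to
#'   skip).
#' @return `det`, invisibly.
#' @export
write_detection <- function(det, mask_path = NULL, csv_path = NULL) {
  if (!is.null(mask_path))
    tiff::writeTIFF(det$mask * 1, mask_path)
  if (!is.null(csv_path)) {
    df <- data.frame(x = det$centroids[, 1], y = det$centroids[, 2],
                     area = det$object_areas)
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(det)
}
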