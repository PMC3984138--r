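#' Pearson correlation of channel intensities
#'
#' The classic pixelwise colocalization estimate: sample correlation of
#' the two channels' intensities, optionally restricted to a mask that
#' excludes background pixels. Positive values suggest colocalization,
#' values near zero give no evidence of it, and negative values
#' indicate inversely related intensities.
#'
#' @param ch1,ch2 equal-shape numeric matrices.
#' @param mask optional logical matrix selecting analysis pixels.
#' @return Scalar in `[-1, 1]`.
#' @export
pearson_coloc <- function(ch1, ch2, mask = NULL) {
  stopifnot(all(dim(ch1) == dim(ch2)))
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(ch1)))
    v1 <- ch1[mask > 0]; v2 <- ch2[mask > 0]
  } else {
    v1 <- as.numeric(ch1); v2 <- as.numeric(ch2)
  }
  if (length(v1) < 2 || stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("correlation undefined: constant channel within mask")
  stats::cor(v1, v2)
}

#' Manders colocalization coefficient
#'
#' Fraction of channel-`i` intensity lying over pixels where the
#' reference channel exceeds a threshold `T`:
#' `M_i = sum(ch_i[ch_ref > T]) / sum(ch_i)`, sums over the mask.
#' Threshold selection is not trivial; the default is Otsu's threshold
#' on the reference channel (within the mask), with a numeric override.
#'
#' @param ch_i channel whose colocalized signal fraction is measured.
#' @param ch_ref reference channel providing the thresholded region.
#' @param threshold numeric threshold `T >= 0`, or `"otsu"` (default).
#' @param mask optional logical matrix of analysis pixels.
#' @return Fraction in `[0, 1]`.
#' @export
manders_coloc <- function(ch_i, ch_ref, threshold = "otsu", mask = NULL) {
  stopifnot(all(dim(ch_i) == dim(ch_ref)))
  sel <- if (is.null(mask)) rep(TRUE, length(ch_i)) else as.logical(mask > 0)
  vi <- ch_i[sel]; vr <- ch_ref[sel]
  if (identical(threshold, "otsu")) {
    rng <- range(vr)
    if (diff(rng) == 0) stop("cannot auto-threshold a constant reference")
    h <- matrix(vr, nrow = 1)
    threshold <- EBImage::otsu(EBImage::Image(h), range = rng, levels = 256)
  }
  stopifnot(is.numeric(threshold), threshold >= 0)
  total <- sum(vi)
  if (total <= 0) stop("Manders coefficient undefined: zero total signal")
  sum(vi[vr > threshold]) / total
}

#' Pixel overlap fraction of two binary masks
#'
#' Direct overlap percentage of pixels: the fraction of each mask's
#' foreground that intersects the other mask's foreground.
#'
#' @param mask1,mask2 equal-shape logical (or 0/1) matrices.
#' @return Numeric vector `c(frac1, frac2)`; 0 for an empty mask.
#' @export
overlap_fraction <- function(mask1, mask2) {
  stopifnot(all(dim(mask1) == dim(mask2)))
  m1 <- mask1 > 0; m2 <- mask2 > 0
  both <- sum(m1 & m2)
  c(frac1 = if (sum(m1) > 0) both / sum(m1) else 0,
    frac2 = if (sum(m2) > 0) both / sum(m2) else 0)
}

#' Objectwise overlap between two labeled segmentations
#'
#' Fraction of each channel's objects having at least one pixel
#' overlapping any object of the other channel — the object-based
#' analogue of pixel overlap, computed from the same segmentation
#' masks.
#'
#' @param labels1,labels2 equal-shape integer label matrices
#'   (0 = background).
#' @return Numeric vector `c(frac1, frac2)`; 0 for an empty channel.
#' @export
object_overlap <- function(labels1, labels2) {
  stopifnot(all(dim(labels1) == dim(labels2)))
  n1 <- length(setdiff(unique(as.integer(labels1)), 0L))
  n2 <- length(setdiff(unique(as.integer(labels2)), 0L))
  hit1 <- length(unique(labels1[labels1 > 0 & labels2 > 0]))
  hit2 <- length(unique(labels2[labels1 > 0 & labels2 > 0]))
  c(frac1 = if (n1 > 0) hit1 / n1 else 0,
    frac2 = if (n2 > 0) hit2 / n2 else 0)
}

#' All pixelwise colocalization estimates at once
#'
#' Convenience wrapper computing Pearson correlation, both Manders
#' coefficients and the mask overlap fractions for a channel pair, the
#' comparison baseline set used alongside the point-pattern association
#' estimate.
#'
#' @param ch1,ch2 intensity matrices.
#' @param mask1,mask2 optional per-channel binary masks (from spot
#'   detection); their union is used as the analysis mask for the
#'   intensity statistics.
#' @param threshold Manders threshold passed to [manders_coloc()].
#' @return A list of class `coloc_result` with `pearson_r`,
#'   `manders_m1`, `manders_m2`, `overlap_frac_ch1`, `overlap_frac_ch2`,
#'   `n_mask_pixels`.
#' @export
coloc_estimates <- function(ch1, ch2, mask1 = NULL, mask2 = NULL,
                            threshold = "otsu") {
  mask <- NULL
  if (!is.null(mask1) && !is.null(mask2)) mask <- (mask1 > 0) | (mask2 > 0)
  res <- list(
    pearson_r = pearson_coloc(ch1, ch2, mask),
    manders_m1 = manders_coloc(ch1, ch2, threshold, mask),
    manders_m2 = manders_coloc(ch2, ch1, threshold, mask),
    overlap_frac_ch1 = NA_real_, overlap_frac_ch2 = NA_real_,
    n_mask_pixels = if (is.null(mask)) length(ch1) else sum(mask))
  if (!is.null(mask1) && !is.null(mask2)) {
    ov <- overlap_fraction(mask1, mask2)
    res$overlap_frac_ch1 <- unname(ov[1])
    res$overlap_frac_ch2 <- unname(ov[2])
  }
  structure(res, class = "coloc_result")
}
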