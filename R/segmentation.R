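#' HSV threshold mask
#'
#' First segmentation component: a pixel belongs to the fruit candidate mask
#' when the ratio of saturation to value exceeds `s_over_v` AND saturation
#' exceeds `s_min`. Both inequalities are strict; pixels with value 0 (hue
#' and the ratio undefined) are always background.
#'
#' @param image RGB array (h x w x 3) with values in \[0, 1\].
#' @param s_over_v threshold on S/V (default 0.2).
#' @param s_min threshold on S (default 0.19).
#' @return Logical matrix.
#' @export
hsv_mask <- function(image, s_over_v = 0.2, s_min = 0.19) {
  hsv <- image_hsv(image)
  ratio_ok <- hsv$v > 0 & hsv$s > s_over_v * hsv$v
  ratio_ok & hsv$s > s_min
}

#' Otsu threshold of a numeric sample
#'
#' Exhaustive maximization of the between-class variance over the boundaries
#' of a fixed-bin histogram spanning the observed range. Ties resolve to the
#' lowest threshold.
#'
#' @param x numeric vector (or matrix) of values.
#' @param levels number of histogram bins.
#' @return The threshold value (a bin boundary), or NA when `x` is constant.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- as.vector(x)
  rng <- range(x)
  if (!is.finite(diff(rng)) || diff(rng) == 0) return(NA_real_)
  edges <- seq(rng[1], rng[2], length.out = levels + 1L)
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
              levels)
  counts <- as.numeric(tabulate(bin, nbins = levels))
  mids <- (edges[-1L] + edges[-(levels + 1L)]) / 2
  w0 <- cumsum(counts)
  s0 <- cumsum(counts * mids)
  n <- w0[levels]; stot <- s0[levels]
  k <- seq_len(levels - 1L)  # split after bin k, threshold = edges[k + 1]
  w1 <- n - w0[k]
  valid <- w0[k] > 0 & w1 > 0
  bcv <- rep(-Inf, levels - 1L)
  bcv[valid] <- (stot * w0[k] - s0[k] * n)[valid]^2 /
    (w0[k] * w1)[valid]
  edges[which.max(bcv) + 1L]
}

#' Background-difference mask
#'
#' Second segmentation component: the per-pixel difference between the fruit
#' image and the matching empty-box image is reduced to a magnitude and
#' thresholded with Otsu's method.
#'
#' @param image,background RGB arrays of identical dimensions.
#' @param metric how the 3-channel difference is reduced to one magnitude:
#'   `"max"` (default; per-pixel maximum of the absolute channel
#'   differences, robust to a fruit matching the background in one
#'   channel), `"luminance"` (absolute difference of channel means) or
#'   `"euclidean"`.
#' @param levels histogram bins for the Otsu threshold.
#' @return Logical matrix; when the image equals the background everywhere
#'   the mask is empty and carries attribute `constant_difference = TRUE`
#'   (with a warning).
#' @export
background_diff_mask <- function(image, background,
                                 metric = c("max", "luminance", "euclidean"),
                                 levels = 256L) {
  metric <- match.arg(metric)
  assert_rgb(image); assert_rgb(background, "background")
  if (!identical(dim(image), dim(background)))
    stop("image and background dimensions differ", call. = FALSE)
  ad <- abs(image - background)
  d <- switch(metric,
    max = pmax(ad[, , 1], ad[, , 2], ad[, , 3]),
    luminance = abs((image[, , 1] + image[, , 2] + image[, , 3]) -
                    (background[, , 1] + background[, , 2] +
                     background[, , 3])) / 3,
    euclidean = sqrt(ad[, , 1]^2 + ad[, , 2]^2 + ad[, , 3]^2))
  thr <- otsu_threshold(d, levels = levels)
  if (is.na(thr)) {
    warning("image and background are identical; empty difference mask")
    return(structure(matrix(FALSE, nrow(d), ncol(d)),
                     constant_difference = TRUE))
  }
  d > thr
}

# largest 8-connected foreground component of a logical matrix
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  if (max(lab) < 1) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

fill_holes <- function(mask) {
  out <- EBImage::fillHull(EBImage::Image(mask * 1))
  EBImage::imageData(out) > 0.5
}

#' Segment one fruit image
#'
#' Combines the HSV threshold mask (`m1`) and the background-difference
#' Otsu mask (`m2`); the fruit area is the set union of both, post-processed
#' by keeping the largest connected component and filling holes. Both
#' component masks are retained for auditing.
#'
#' @param image,background RGB arrays of identical dimensions.
#' @param image_id identifier used in error messages and provenance.
#' @param postprocess set FALSE to return the raw union.
#' @param exclusion optional logical matrix; TRUE pixels (e.g. a pedestal
#'   region) are removed from both masks before post-processing.
#' @inheritParams background_diff_mask
#' @inheritParams hsv_mask
#' @return Object of class `fruit_segmentation`: list with `mask`, `m1`,
#'   `m2`, `area_px`, `source_image_id`.
#' @export
segment_fruit <- function(image, background, image_id = "image",
                          s_over_v = 0.2, s_min = 0.19,
                          metric = "max", postprocess = TRUE,
                          exclusion = NULL) {
  m1 <- hsv_mask(image, s_over_v = s_over_v, s_min = s_min)
  m2 <- background_diff_mask(image, background, metric = metric)
  u <- m1 | m2
  if (!is.null(exclusion)) u <- u & !exclusion
  if (!any(u))
    stop("no fruit detected in '", image_id, "'", call. = FALSE)
  mask <- if (postprocess) fill_holes(largest_component(u)) else u
  structure(list(mask = mask, m1 = m1, m2 = m2,
                 area_px = sum(mask), source_image_id = image_id),
            class = "fruit_segmentation")
}
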