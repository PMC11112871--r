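#' Convert a binary mask to a 360-degree polar radius profile
#'
#' Casts one ray per integer degree from the mask centroid and records the
#' distance to the outer boundary. The mask is sampled with bilinear
#' interpolation and the boundary is located at the 0.5 iso-level, giving
#' sub-pixel radii. For boundaries that are not star-shaped with respect to
#' the centroid the outermost 0.5-crossing is taken.
#'
#' Angles follow the mathematical convention: 0 degrees along +x (increasing
#' image column), counter-clockwise, with the image row axis flipped so that
#' +y points up.
#'
#' @param mask logical or 0/1 matrix with a single filled foreground
#'   component.
#' @param view `"side"` or `"top"`; stored on the result.
#' @param step ray sampling step in pixels.
#' @return An object of class `polar_profile`: a list with `radius_deg`
#'   (360 radii in pixels, index i = degree i-1), `centroid` (col, row),
#'   `view`, and `symmetry_angle_deg` (NA until [symmetrize()] is applied).
#' @seealso [top_circles()], [symmetrize()], [polar_area()]
#' @export
to_polar <- function(mask, view = c("side", "top"), step = 0.25) {
  view <- match.arg(view)
  m <- assert_mask(mask)
  mm <- matrix(as.numeric(m), nrow(m), ncol(m))
  ctr <- mask_centroid(m)
  idx <- which(m)
  nr <- nrow(m)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  rmax <- sqrt(max((cols - ctr["col"])^2 + (rows - ctr["row"])^2)) + 2
  t_grid <- seq(step, rmax, by = step)
  theta <- (0:359) * pi / 180
  # sample all rays at once: columns = angles, rows = distances
  cc <- ctr[["col"]] + outer(t_grid, cos(theta))
  rr <- ctr[["row"]] - outer(t_grid, sin(theta))
  vals <- matrix(bilinear_sample(mm, as.vector(rr), as.vector(cc)),
                 nrow = length(t_grid))
  inside <- vals >= 0.5
  radius <- vapply(seq_len(360L), function(j) {
    i <- which(inside[, j])
    if (!length(i))
      stop("ray at degree ", j - 1L,
           " does not intersect the mask; centroid outside mask?",
           call. = FALSE)
    i <- max(i)
    if (i == length(t_grid)) return(t_grid[i])
    v0 <- vals[i, j]; v1 <- vals[i + 1L, j]
    if (v0 <= v1) return(t_grid[i])
    t_grid[i] + step * (v0 - 0.5) / (v0 - v1)
  }, numeric(1))
  structure(list(radius_deg = radius, centroid = ctr, view = view,
                 symmetry_angle_deg = NA_real_),
            class = "polar_profile")
}

#' Polygon area enclosed by a polar radius profile
#'
#' Area of the 360-gon defined by the per-degree radii; used to check that a
#' profile is consistent with the pixel area of the mask it came from.
#'
#' @param radius_deg numeric vector of 360 radii.
#' @return Area in squared pixels.
#' @export
polar_area <- function(radius_deg) {
  r <- if (inherits(radius_deg, "polar_profile")) radius_deg$radius_deg
       else radius_deg
  stopifnot(length(r) == 360L)
  r2 <- c(r[-1L], r[1L])
  sum(0.5 * r * r2 * sin(pi / 180))
}

# true-pixel coordinates of a mask as a two-column matrix (col, row)
mask_coords <- function(m) {
  idx <- which(m)
  nr <- nrow(m)
  cbind(col = ((idx - 1L) %/% nr) + 1L, row = ((idx - 1L) %% nr) + 1L)
}

# asymmetry index from explicit pixel coordinates; cx = mirror axis column
asymmetry_from_coords <- function(cols, rows, cx) {
  n <- length(cols)
  mcols <- round(2 * cx - cols)
  key <- rows * 2e5 + cols
  mkey <- rows * 2e5 + mcols
  inter <- sum(mkey %in% key)
  (2 * n - 2 * inter) / (2 * n)
}

#' Mirror-asymmetry index of a mask
#'
#' The mask is mirrored across the vertical axis through its centroid and
#' the area of the symmetric difference between original and mirrored mask
#' is divided by twice the mask area. The index is 0 for perfectly
#' mirror-symmetric shapes and at most 1.
#'
#' Mirroring is pixel-exact: column c maps to round(2 * cx - c) where cx is
#' the centroid column, so a pixel-symmetric mask (e.g. an odd-sized
#' centered disk) scores exactly 0.
#'
#' @param mask logical or 0/1 matrix, non-empty.
#' @return Asymmetry index in \[0, 1\].
#' @export
asymmetry_index <- function(mask) {
  m <- assert_mask(mask)
  xy <- mask_coords(m)
  cx <- mean(xy[, "col"])
  asymmetry_from_coords(xy[, "col"], xy[, "row"], cx)
}

#' Rotate a binary mask about a point
#'
#' Nearest-neighbour inverse-mapped rotation (keeps the mask strictly
#' binary). Positive angles rotate counter-clockwise in the mathematical
#' orientation (image y flipped).
#'
#' @param mask logical or 0/1 matrix.
#' @param angle_deg rotation angle in degrees.
#' @param center optional c(col, row) rotation center; defaults to the mask
#'   centroid.
#' @return Logical matrix of the same dimensions.
#' @export
rotate_mask <- function(mask, angle_deg, center = NULL) {
  m <- assert_mask(mask)
  if (angle_deg == 0) return(m)
  ctr <- center %||% mask_centroid(m)
  a <- -angle_deg * pi / 180  # inverse map; row axis flip absorbs sign
  nr <- nrow(m); nc <- ncol(m)
  cols <- rep(seq_len(nc), each = nr)
  rows <- rep(seq_len(nr), times = nc)
  dx <- cols - ctr[["col"]]
  dy <- -(rows - ctr[["row"]])
  sx <- ctr[["col"]] + cos(a) * dx - sin(a) * dy
  sy <- ctr[["row"]] - (sin(a) * dx + cos(a) * dy)
  si <- round(sx); sj <- round(sy)
  ok <- si >= 1L & si <= nc & sj >= 1L & sj <= nr
  out <- logical(nr * nc)
  out[ok] <- m[cbind(sj[ok], si[ok])]
  matrix(out, nr, nc)
}

#' Rotate a mask to minimize its mirror asymmetry
#'
#' Searches rotations about the centroid on a regular grid and returns the
#' angle whose rotated mask has the smallest [asymmetry_index()]. Ties are
#' broken toward the smallest absolute angle, negative before positive.
#'
#' @param mask logical or 0/1 matrix.
#' @param range_deg half-width of the search window in degrees.
#' @param step_deg grid step in degrees.
#' @return List with `symmetry_angle_deg` (applied rotation), `mask`
#'   (rotated mask) and `asymmetry` (minimal index).
#' @export
symmetrize <- function(mask, range_deg = 20, step_deg = 0.25) {
  m <- assert_mask(mask)
  ctr <- mask_centroid(m)
  xy <- mask_coords(m)
  # evaluate rotations on a bounding window that always contains the shape
  rmax <- sqrt(max((xy[, "col"] - ctr["col"])^2 +
                   (xy[, "row"] - ctr["row"])^2)) + 2
  c0 <- floor(ctr[["col"]] - rmax); c1 <- ceiling(ctr[["col"]] + rmax)
  r0 <- floor(ctr[["row"]] - rmax); r1 <- ceiling(ctr[["row"]] + rmax)
  gc_ <- rep(c0:c1, each = r1 - r0 + 1L)
  gr_ <- rep(r0:r1, times = c1 - c0 + 1L)
  dx <- gc_ - ctr[["col"]]
  dy <- -(gr_ - ctr[["row"]])
  nr <- nrow(m); nc <- ncol(m)
  angles <- seq(-range_deg, range_deg, by = step_deg)
  # order so that ties resolve to smallest |angle|, negative before positive
  angles <- angles[order(abs(angles), angles)]
  eval_angle <- function(ang) {
    a <- -ang * pi / 180
    sx <- ctr[["col"]] + cos(a) * dx - sin(a) * dy
    sy <- ctr[["row"]] - (sin(a) * dx + cos(a) * dy)
    si <- round(sx); sj <- round(sy)
    ok <- si >= 1L & si <= nc & sj >= 1L & sj <= nr
    inside <- logical(length(ok))
    inside[ok] <- m[cbind(sj[ok], si[ok])]
    cols <- gc_[inside]; rows <- gr_[inside]
    asymmetry_from_coords(cols, rows, mean(cols))
  }
  asym <- vapply(angles, eval_angle, numeric(1))
  best <- which.min(asym)  # first minimum in tie-break order
  list(symmetry_angle_deg = angles[best],
       mask = rotate_mask(m, angles[best], center = ctr),
       asymmetry = asym[best])
}

#' Calibrated width and height of a mask
#'
#' Horizontal and vertical pixel extents (max - min occupied coordinate + 1)
#' scaled by the camera calibration.
#'
#' @param mask logical or 0/1 matrix.
#' @param cm_per_px calibration factor, centimeters per pixel, > 0.
#' @return Named vector c(width_cm, height_cm).
#' @export
dimensions <- function(mask, cm_per_px) {
  stopifnot(is.numeric(cm_per_px), cm_per_px > 0)
  m <- assert_mask(mask)
  xy <- mask_coords(m)
  c(width_cm = (diff(range(xy[, "col"])) + 1) * cm_per_px,
    height_cm = (diff(range(xy[, "row"])) + 1) * cm_per_px)
}

#' Top-view circle metrics from a polar profile
#'
#' With the origin fixed at the contour centroid: the circumcircle radius is
#' the largest boundary radius, the incircle radius the smallest, plus the
#' mean radius and the standard deviation of the radii after normalizing the
#' mean radius to 1 (a unitless roundness measure).
#'
#' @param profile a [to_polar()] result (any view accepted; intended for
#'   top views) or a numeric vector of 360 radii.
#' @return List with `radius_mean_px`, `radius_in_px`, `radius_circ_px`,
#'   `radius_std_nor`.
#' @export
top_circles <- function(profile) {
  r <- if (inherits(profile, "polar_profile")) profile$radius_deg else profile
  stopifnot(is.numeric(r), length(r) == 360L, all(r > 0))
  mu <- mean(r)
  list(radius_mean_px = mu,
       radius_in_px = min(r),
       radius_circ_px = max(r),
       radius_std_nor = stats::sd(r / mu))
}

#' Export a polar profile as a plain-text table
#'
#' Writes one row per integer degree with the radius in pixels and, when a
#' calibration is given, in centimeters, plus the Cartesian boundary
#' coordinates relative to the centroid.
#'
#' @param profile a [to_polar()] result.
#' @param path output file path (tab-delimited text).
#' @param cm_per_px optional calibration to add radius_cm, x_cm, y_cm.
#' @return The exported data frame, invisibly.
#' @export
export_profile <- function(profile, path, cm_per_px = NULL) {
  stopifnot(inherits(profile, "polar_profile"))
  deg <- 0:359
  r <- profile$radius_deg
  out <- data.frame(degree = deg, radius_px = r,
                    x_px = r * cos(deg * pi / 180),
                    y_px = r * sin(deg * pi / 180))
  if (!is.null(cm_per_px)) {
    out$radius_cm <- r * cm_per_px
    out$x_cm <- out$x_px * cm_per_px
    out$y_cm <- out$y_px * cm_per_px
  }
  utils::write.table(format(out, digits = 6, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
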