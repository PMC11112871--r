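# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures.

disk_mask <- function(n, r) {
  cc <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) (i - cc)^2 + (j - cc)^2 <= r^2)
}

ellipse_mask <- function(nr, nc, a, b) {
  cy <- (nr + 1) / 2
  cx <- (nc + 1) / 2
  outer(1:nr, 1:nc, function(i, j) ((j - cx) / a)^2 + ((i - cy) / b)^2 <= 1)
}

square_mask <- function(n, side) {
  cc <- (n + 1) / 2
  h <- side / 2
  outer(1:n, 1:n, function(i, j) abs(i - cc) <= h & abs(j - cc) <= h)
}

# smooth star-shaped random blob, guaranteed single filled component
random_blob <- function(n = 151, r0 = 45, seed = 1) {
  set.seed(seed)
  k <- 2:5
  amp <- runif(length(k), 0, 0.08)
  ph <- runif(length(k), 0, 2 * pi)
  cc <- (n + 1) / 2
  th <- outer(1:n, 1:n, function(i, j) atan2(-(i - cc), j - cc))
  rr <- outer(1:n, 1:n, function(i, j) sqrt((i - cc)^2 + (j - cc)^2))
  rad <- r0 * (1 + Reduce(`+`, lapply(seq_along(k), function(m)
    amp[m] * cos(k[m] * th + ph[m]))))
  rr <= rad
}

# independent mirror-asymmetry oracle: explicit per-pixel XOR count using a
# matrix-lookup mirror, no shared code with asymmetry_index(). The frame is
# padded so the mirrored shape never leaves it.
oracle_mirror_asym <- function(mask) {
  m0 <- mask > 0.5
  pad <- ncol(m0)
  m <- cbind(matrix(FALSE, nrow(m0), pad), m0, matrix(FALSE, nrow(m0), pad))
  nr <- nrow(m); nc <- ncol(m)
  cols <- col(m)[m]
  cx <- mean(cols)
  xor_count <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    jj <- round(2 * cx - j)
    mirrored <- jj >= 1 && jj <= nc && m[i, jj]
    if (xor(m[i, j], mirrored)) xor_count <- xor_count + 1L
  }
  xor_count / (2 * sum(m))
}

# naive exhaustive Otsu oracle on the same 256-bin discretization
oracle_otsu <- function(x, levels = 256L) {
  x <- as.vector(x)
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  edges <- seq(rng[1], rng[2], length.out = levels + 1L)
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
              levels)
  counts <- tabulate(bin, nbins = levels)
  mids <- (edges[-1L] + edges[-(levels + 1L)]) / 2
  best_k <- NA_integer_; best_v <- -Inf
  for (k in seq_len(levels - 1L)) {
    n0 <- sum(counts[1:k]); n1 <- sum(counts[(k + 1):levels])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / n0
    mu1 <- sum(counts[(k + 1):levels] * mids[(k + 1):levels]) / n1
    v <- (n0 / (n0 + n1)) * (n1 / (n0 + n1)) * (mu0 - mu1)^2
    if (v > best_v) { best_v <- v; best_k <- k }
  }
  edges[best_k + 1L]
}

# intersection-over-union with a 1-px band around the truth outline excluded
band_excluded_iou <- function(pred, truth) {
  t1 <- EBImage::Image(truth * 1)
  brush <- EBImage::makeBrush(3, "box")
  band <- (EBImage::imageData(EBImage::dilate(t1, brush)) > 0.5) &
    !(EBImage::imageData(EBImage::erode(t1, brush)) > 0.5)
  keep <- !band
  p <- pred & keep; t <- truth & keep
  sum(p & t) / sum(p | t)
}

# solid-color image in HSV with an optional foreground disk
flat_hsv_image <- function(nr, nc, h, s, v) {
  rgb <- fruitmorph:::hsv_to_rgb(h, s, v)
  array(rep(rgb, each = nr * nc), c(nr, nc, 3))
}

# small rendered fruit used by several suites (fast frame)
quick_render <- function(side = ellipse_profile(3.2, 2.9),
                         top = circle_profile(3.0),
                         mixture = data.frame(h = 0, s = 0.9, v = 0.8,
                                              weight = 1),
                         weight_g = 150, skew = 0, seed = 1,
                         cm_per_px = 0.04, width = 324, height = 270) {
  spec <- fruit_spec(side, top, peel_hue_mixture = mixture,
                     weight_g = weight_g, asymmetry_skew = skew,
                     rng_seed = seed)
  render_fruit(spec, calibration = cm_per_px, width = width,
               height = height)
}

# tapered (ovoid) side profile in cm; shear on this shape is not removable
# by rotation, so it carries genuine asymmetry
ovoid_profile_cm <- function(scale = 3.0) {
  fruitmorph:::parametric_outline(aspect = 1.1, p = 2, taper = 0.3) * scale
}
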