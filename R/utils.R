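# Internal helpers shared across modules.
#
# Image convention: numeric array h x w x 3 with values in [0, 1], row 1 at
# the top of the frame (as returned by tiff::readTIFF). Masks are logical
# h x w matrices. Geometry uses the mathematical orientation: angle 0 deg
# points along +x (increasing column), angles increase counter-clockwise,
# which means the image row axis is flipped (dy_row = -sin(theta)).

assert_rgb <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] < 3L)
    stop(sprintf("`%s` must be an RGB array (h x w x 3)", arg), call. = FALSE)
  invisible(image)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask))
    stop(sprintf("`%s` must be a matrix", arg), call. = FALSE)
  m <- if (is.logical(mask)) mask else mask > 0.5
  if (!any(m))
    stop(sprintf("`%s` is empty (no foreground pixels)", arg), call. = FALSE)
  m
}

# Per-pixel HSV components of an RGB array; h, s, v in [0, 1].
image_hsv <- function(image) {
  assert_rgb(image)
  d <- dim(image)
  rgb <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  list(h = matrix(hsv[1L, ], d[1], d[2]),
       s = matrix(hsv[2L, ], d[1], d[2]),
       v = matrix(hsv[3L, ], d[1], d[2]))
}

# Vectorized HSV -> RGB in double precision (grDevices::hsv returns 8-bit
# hex strings, too coarse for 16-bit rendering).
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

# Snap to the 16-bit quantization grid used for TIFF output.
quantize16 <- function(x) {
  round(pmin(pmax(x, 0), 1) * 65535) / 65535
}

# Bilinear interpolation of a numeric matrix at fractional (row, col)
# positions; coordinates are clamped to the matrix extent.
bilinear_sample <- function(mat, row, col) {
  nr <- nrow(mat); nc <- ncol(mat)
  row <- pmin(pmax(row, 1), nr)
  col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(row), nr - 1L); c0 <- pmin(floor(col), nc - 1L)
  fr <- row - r0; fc <- col - c0
  v00 <- mat[cbind(r0, c0)]
  v10 <- mat[cbind(r0 + 1L, c0)]
  v01 <- mat[cbind(r0, c0 + 1L)]
  v11 <- mat[cbind(r0 + 1L, c0 + 1L)]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

# Centroid (center of mass) of a mask in pixel coordinates.
# Returns c(col, row).
mask_centroid <- function(mask) {
  m <- assert_mask(mask)
  idx <- which(m)
  nr <- nrow(m)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  c(col = mean(cols), row = mean(rows))
}

# Run code with a private RNG stream, leaving the global .Random.seed
# untouched; seed = NULL runs with the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
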