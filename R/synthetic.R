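# Synthetic five-view fruit renderer.
#
# Renders parametric star-shaped fruit outlines into the same five-camera
# frame geometry the imaging box produces (cameras 1-4 side, 5 top),
# together with the matching empty-background images and ground-truth
# masks. Everything downstream (segmentation, geometry, color, records) can
# be validated against the known truth without any camera hardware. The
# renderer is deliberately non-photorealistic: flat peel colors drawn from
# an HSV mixture, a uniform low-saturation background, no lighting or lens
# model.

#' Analytic polar profiles
#'
#' Helper profiles for building [fruit_spec()] objects: a circle of radius
#' `r` and an axis-aligned ellipse with semi-axes `a` (horizontal) and `b`
#' (vertical), both as radius-per-integer-degree vectors about the center.
#'
#' @param r,a,b radii / semi-axes (any unit).
#' @return Numeric vector of 360 radii.
#' @export
circle_profile <- function(r) rep(as.numeric(r), 360L)

#' @rdname circle_profile
#' @export
ellipse_profile <- function(a, b) {
  th <- (0:359) * pi / 180
  a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
}

#' Specification of a synthetic fruit
#'
#' Ground-truth description of one fruit: side and top outline profiles (in
#' cm about the outline centroid), a peel color mixture in HSV, the fruit
#' weight, and a shear parameter that introduces a known, view-dependent
#' asymmetry into the side views.
#'
#' @param side_radius_profile,top_radius_profile numeric vectors of 360
#'   strictly positive radii in cm.
#' @param peel_hue_mixture data frame with columns `h` (in \[0, 1)), `s`,
#'   `v` (in (0, 1\]) and `weight` (non-negative, summing to 1).
#' @param weight_g fruit mass in grams, > 0.
#' @param asymmetry_skew dimensionless shear, >= 0; 0 renders symmetric
#'   side views.
#' @param rng_seed integer seed for the per-pixel color sampling.
#' @return Object of class `fruit_spec`.
#' @export
fruit_spec <- function(side_radius_profile, top_radius_profile,
                       peel_hue_mixture = data.frame(h = 0, s = 0.9,
                                                     v = 0.8, weight = 1),
                       weight_g = 150, asymmetry_skew = 0, rng_seed = 1L) {
  for (p in list(side_radius_profile, top_radius_profile)) {
    if (length(p) != 360L || !all(is.finite(p)) || any(p <= 0))
      stop("radius profiles must be 360 finite positive values",
           call. = FALSE)
  }
  mx <- as.data.frame(peel_hue_mixture)
  stopifnot(all(c("h", "s", "v", "weight") %in% names(mx)))
  if (abs(sum(mx$weight) - 1) > 1e-9)
    stop("peel_hue_mixture weights must sum to 1", call. = FALSE)
  stopifnot(all(mx$weight >= 0), all(mx$h >= 0 & mx$h < 1),
            all(mx$s > 0 & mx$s <= 1), all(mx$v > 0 & mx$v <= 1))
  stopifnot(weight_g > 0, asymmetry_skew >= 0)
  structure(list(side_radius_profile = as.numeric(side_radius_profile),
                 top_radius_profile = as.numeric(top_radius_profile),
                 peel_hue_mixture = mx, weight_g = weight_g,
                 asymmetry_skew = asymmetry_skew,
                 rng_seed = as.integer(rng_seed)),
            class = "fruit_spec")
}

# background of the synthetic box: neutral gray, S = 0.05, V = 0.9, which
# fails both HSV thresholds of mask m1 with margin
.render_background_hsv <- c(h = 0.10, s = 0.05, v = 0.90)

# per-camera shear multipliers for the side views
.shear_factors <- c(1, 0.5, -0.5, -1)

render_one_view <- function(radius_cm, shear, cm_per_px, width, height,
                            mixture, seed) {
  maxr_px <- max(radius_cm) * (1 + abs(shear)) / cm_per_px
  if (2 * (maxr_px + 2) > min(width, height))
    stop("fruit larger than frame at the given calibration", call. = FALSE)
  cx <- (width + 1) / 2; cy <- (height + 1) / 2
  col <- rep(seq_len(width), each = height)
  row <- rep(seq_len(height), times = width)
  x <- (col - cx) * cm_per_px
  y <- -(row - cy) * cm_per_px
  xq <- x - shear * y
  rho <- sqrt(xq^2 + y^2)
  th <- (atan2(y, xq) * 180 / pi) %% 360
  rprof <- stats::approx(0:360, c(radius_cm, radius_cm[1L]), xout = th)$y
  cov <- pmin(pmax((rprof - rho) / cm_per_px + 0.5, 0), 1)
  bg_rgb <- hsv_to_rgb(.render_background_hsv["h"],
                       .render_background_hsv["s"],
                       .render_background_hsv["v"])
  img <- array(rep(bg_rgb, each = height * width), c(height, width, 3L))
  fr <- which(cov > 0)
  if (length(fr)) {
    comp <- with_seed(seed,
      sample.int(nrow(mixture), length(fr), replace = TRUE,
                 prob = mixture$weight))
    rgb <- hsv_to_rgb(mixture$h[comp], mixture$s[comp], mixture$v[comp])
    a <- cov[fr]
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[cbind(row[fr], col[fr])] <-
        (1 - a) * bg_rgb[ch] + a * rgb[, ch]
      img[, , ch] <- plane
    }
  }
  mask <- matrix(FALSE, height, width)
  mask[cbind(row[cov >= 0.5], col[cov >= 0.5])] <- TRUE
  list(image = quantize16(img),
       background = quantize16(array(rep(bg_rgb, each = height * width),
                                     c(height, width, 3L))),
       mask = mask)
}

#' Render the five views of a synthetic fruit
#'
#' Cameras 1-4 render the side profile, each sheared by
#' `asymmetry_skew * f(k)` with f = (1, 0.5, -0.5, -1) so a non-zero skew
#' produces a known, view-dependent asymmetry; camera 5 renders the top
#' profile. The fruit is centered in the frame on a uniform low-saturation
#' gray background; peel pixels draw their HSV color independently from the
#' spec's mixture under the spec's seed. Images are quantized to the 16-bit
#' grid used for TIFF output. An antialiasing band of at most 1 px
#' surrounds the true outline; the ground-truth mask is the 50% coverage
#' set.
#'
#' @param spec a [fruit_spec()].
#' @param calibration cm-per-pixel, one value per camera (length 1 or 5).
#' @param width,height frame size in pixels.
#' @return Object of class `rendered_fruit`: lists `images`,
#'   `backgrounds`, `truth_masks` (camera 1-5), plus `spec` and
#'   `calibration`.
#' @export
render_fruit <- function(spec, calibration = 0.01, width = 1296L,
                         height = 1080L) {
  stopifnot(inherits(spec, "fruit_spec"))
  calibration <- rep_len(as.numeric(calibration), 5L)
  if (any(calibration <= 0)) stop("calibration must be positive",
                                  call. = FALSE)
  views <- vector("list", 5L)
  for (k in 1:4) {
    views[[k]] <- render_one_view(spec$side_radius_profile,
                                  spec$asymmetry_skew * .shear_factors[k],
                                  calibration[k], width, height,
                                  spec$peel_hue_mixture,
                                  spec$rng_seed + k)
  }
  views[[5L]] <- render_one_view(spec$top_radius_profile, 0, calibration[5L],
                                 width, height, spec$peel_hue_mixture,
                                 spec$rng_seed + 5L)
  structure(list(images = lapply(views, `[[`, "image"),
                 backgrounds = lapply(views, `[[`, "background"),
                 truth_masks = lapply(views, `[[`, "mask"),
                 spec = spec, calibration = calibration),
            class = "rendered_fruit")
}

#' Write a rendered fruit to the acquisition directory layout
#'
#' Stores the five views as 16-bit packbits TIFF files under
#' `root/images/<id>/cam<N>/` using the acquisition filename dialect, the
#' empty-background references under `root/background/cam<N>.tif` (written
#' once), and the fruit weight in a per-directory `manifest.tsv` sidecar
#' (filename, weight_g).
#'
#' @param sample a [render_fruit()] result.
#' @param root acquisition root directory (created if needed).
#' @param id sample/tree identifier (the barcode text).
#' @param index fruit index, >= 1.
#' @param timestamp a POSIXct (or anything `format()`-able to date + time);
#'   default a fixed reference time so runs are reproducible.
#' @return Character vector of the five image paths written.
#' @export
write_sample <- function(sample, root, id, index,
                         timestamp = as.POSIXct("2021-09-15 10:00:00",
                                                tz = "UTC")) {
  stopifnot(inherits(sample, "rendered_fruit"))
  paths <- character(5L)
  for (cam in 1:5) {
    dir <- file.path(root, "images", id, sprintf("cam%d", cam))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fn <- fruit_filename(id, cam, index, timestamp)
    path <- file.path(dir, fn)
    if (file.exists(path))
      stop("refusing to overwrite existing image ", path, call. = FALSE)
    write_fruit_image(sample$images[[cam]], path,
                      weight_g = sample$spec$weight_g)
    bgdir <- file.path(root, "background")
    dir.create(bgdir, showWarnings = FALSE, recursive = TRUE)
    bgpath <- file.path(bgdir, sprintf("cam%d.tif", cam))
    if (!file.exists(bgpath))
      write_fruit_image(sample$backgrounds[[cam]], bgpath)
    paths[cam] <- path
  }
  paths
}

#' Simulate a record-level phenotyping study
#'
#' Draws per-fruit trait values (width, height, weight) for a set of
#' cultivars with programmed per-cultivar means, without rendering images.
#' Widths and heights are independent normals with cultivar-specific means
#' and common coefficients of variation; programmed mean weights follow a
#' spheroid-volume model (density x pi/6 x width^2 x height). The defaults
#' mirror a realistic apple study: 15 cultivars, 100 fruit each, trait CVs
#' of about 5.5% (width), 6.5% (height) and 15.5% (weight).
#'
#' @param n_cultivars,n_fruit study size.
#' @param width_means,height_means programmed per-cultivar means in cm
#'   (recycled/defaulted to an evenly spread range).
#' @param weight_means programmed mean weights in g; default derived from
#'   width and height via the spheroid model with density 0.8 g/cm3.
#' @param width_cv,height_cv,weight_cv within-cultivar coefficients of
#'   variation.
#' @param seed RNG seed.
#' @return Data frame with columns `cultivar`, `fruit_index`,
#'   `width_mean_cm`, `height_mean_cm`, `weight_g`, `shape_index`;
#'   attribute `programmed` holds the per-cultivar programmed means.
#' @export
simulate_study <- function(n_cultivars = 15L, n_fruit = 100L,
                           width_means = NULL, height_means = NULL,
                           weight_means = NULL,
                           width_cv = 0.055, height_cv = 0.065,
                           weight_cv = 0.155, seed = 1L) {
  width_means <- width_means %||%
    seq(6.6, 8.4, length.out = n_cultivars)
  height_means <- height_means %||%
    (width_means * seq(0.85, 1.10, length.out = n_cultivars))
  weight_means <- weight_means %||%
    (0.8 * pi / 6 * width_means^2 * height_means)
  stopifnot(length(width_means) == n_cultivars,
            length(height_means) == n_cultivars,
            length(weight_means) == n_cultivars)
  cultivars <- sprintf("CV%02d", seq_len(n_cultivars))
  with_seed(seed, {
    rows <- lapply(seq_len(n_cultivars), function(i) {
      data.frame(cultivar = cultivars[i], fruit_index = seq_len(n_fruit),
                 width_mean_cm = rnorm(n_fruit, width_means[i],
                                       width_means[i] * width_cv),
                 height_mean_cm = rnorm(n_fruit, height_means[i],
                                        height_means[i] * height_cv),
                 weight_g = rnorm(n_fruit, weight_means[i],
                                  weight_means[i] * weight_cv))
    })
    out <- do.call(rbind, rows)
    out$shape_index <- out$height_mean_cm / out$width_mean_cm
    attr(out, "programmed") <-
      data.frame(cultivar = cultivars, width_mean_cm = width_means,
                 height_mean_cm = height_means, weight_g = weight_means)
    out
  })
}
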