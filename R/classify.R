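# Reference-outline library and correlation-based shape classification.
#
# The numeric outlines of the 13 pomological side-shape categories are not
# public as data; the default library is a parametric stand-in built from a
# superellipse family (aspect ratio, squareness, linear taper, waist,
# stem/calyx dip) spanning the named categories, and can be replaced with
# any user library via load_reference_library().

# 360 mean-1 radii of a parametric fruit outline (half-width model).
# aspect = half-height / half-width; p = superellipse exponent; taper > 0
# narrows the top linearly; waist pinches the equator; dip carves
# stem/calyx cavities at 90 and 270 degrees.
parametric_outline <- function(aspect = 1, p = 2, taper = 0, waist = 0,
                               dip = 0) {
  b <- aspect
  y <- seq(-b, b, length.out = 4001)
  u <- pmin(abs(y) / b, 1)
  w <- (1 - u^p)^(1 / p) *
    (1 - taper * (y / b + 1) / 2) *
    (1 - waist * (1 - (y / b)^2))
  w <- pmax(w, 0)
  xs <- c(w, rev(-w)); ys <- c(y, rev(y))
  n <- length(y)
  if (w[n] > 1e-4) {  # top cap of truncated shapes
    xc <- seq(-w[n], w[n], length.out = 201)
    xs <- c(xs, xc); ys <- c(ys, rep(b, 201))
  }
  if (w[1] > 1e-4) {
    xc <- seq(-w[1], w[1], length.out = 201)
    xs <- c(xs, xc); ys <- c(ys, rep(-b, 201))
  }
  y0 <- sum(y * w) / sum(w)  # region centroid (x0 = 0 by symmetry)
  th <- atan2(ys - y0, xs) * 180 / pi
  r <- sqrt(xs^2 + (ys - y0)^2)
  o <- order(th)
  rr <- stats::approx(c(th[o] - 360, th[o], th[o] + 360), rep(r[o], 3),
                      xout = 0:359, ties = mean)$y
  if (dip != 0) {
    d <- 0:359
    rr <- rr * (1 - dip * (exp(-((d - 90) / 12)^2) +
                           exp(-((d - 270) / 12)^2)))
  }
  rr / mean(rr)
}

.side_library_params <- list(
  "spherical"            = list(aspect = 1.00, p = 2.0, dip = 0.06),
  "flattened spherical"  = list(aspect = 0.82, p = 2.2, dip = 0.04),
  "ellipsoid"            = list(aspect = 1.20, p = 2.0),
  "oblong"               = list(aspect = 1.35, p = 2.8),
  "ovoid"                = list(aspect = 1.10, p = 2.0, taper = 0.30),
  "obovoid"              = list(aspect = 1.10, p = 2.0, taper = -0.30),
  "conical"              = list(aspect = 1.00, p = 1.6, taper = 0.50),
  "truncate conical"     = list(aspect = 0.92, p = 3.2, taper = 0.40),
  "rectangular"          = list(aspect = 1.05, p = 5.0),
  "rectangular conical"  = list(aspect = 1.05, p = 4.0, taper = 0.25),
  "cylindrical"          = list(aspect = 1.30, p = 6.0),
  "cylindrical waisted"  = list(aspect = 1.30, p = 6.0, waist = 0.14),
  "globose conical"      = list(aspect = 0.95, p = 2.1, taper = 0.28,
                                dip = 0.05))

.library_cache <- new.env(parent = emptyenv())

new_reference_library <- function(class_id, name, profiles, view) {
  profiles <- profiles / rowMeans(profiles)
  structure(list(class_id = as.integer(class_id), name = name,
                 profiles = profiles, view = view),
            class = "reference_library")
}

#' Built-in reference shape libraries
#'
#' The side library holds 13 parametric outlines named after common
#' pomological shape descriptors (spherical, flattened spherical, ellipsoid,
#' oblong, ovoid, obovoid, conical, truncate conical, rectangular,
#' rectangular conical, cylindrical, cylindrical waisted, globose conical).
#' The top library is a minimal 3-entry placeholder (circular, weakly
#' ribbed, strongly ribbed). Both are mean-1 normalized and can be replaced
#' via [load_reference_library()].
#'
#' @param view `"side"` (13 entries) or `"top"` (3 entries).
#' @return A `reference_library`: list with `class_id`, `name`, `profiles`
#'   (matrix, one row per class, 360 columns) and `view`.
#' @export
default_reference_library <- function(view = c("side", "top")) {
  view <- match.arg(view)
  key <- paste0("default_", view)
  if (!is.null(.library_cache[[key]])) return(.library_cache[[key]])
  if (view == "side") {
    profiles <- t(vapply(.side_library_params,
                         function(p) do.call(parametric_outline, p),
                         numeric(360)))
    lib <- new_reference_library(seq_along(.side_library_params),
                                 names(.side_library_params), profiles,
                                 "side")
  } else {
    d <- (0:359) * pi / 180
    profiles <- rbind(
      circular          = 1 + 0.005 * cos(4 * d),
      `weakly ribbed`   = 1 + 0.050 * cos(5 * d),
      `strongly ribbed` = 1 + 0.090 * cos(5 * d) + 0.050 * cos(10 * d))
    lib <- new_reference_library(1:3, rownames(profiles), profiles, "top")
  }
  .library_cache[[key]] <- lib
  lib
}

#' Read a reference shape library from a text file
#'
#' Expected format: a header line, then one row per class with columns
#' `class_id`, `name`, and 360 radii (whitespace- or comma-delimited;
#' names containing spaces must use delimiter-safe quoting or underscores).
#' Profiles are mean-1 normalized on load.
#'
#' @param path file path; `NULL` returns the built-in default library.
#' @param view which default library to fall back to and to tag the result.
#' @return A `reference_library`.
#' @export
load_reference_library <- function(path = NULL, view = c("side", "top")) {
  view <- match.arg(view)
  if (is.null(path)) return(default_reference_library(view))
  raw <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (ncol(raw) != 362L)
    stop("reference library must have 362 columns (class_id, name, 360 ",
         "radii); found ", ncol(raw), call. = FALSE)
  for (i in seq_len(nrow(raw))) {
    radii <- as.numeric(raw[i, -(1:2)])
    if (anyNA(radii) || any(radii <= 0))
      stop("non-positive or missing radius in reference library row ", i,
           call. = FALSE)
  }
  ids <- as.integer(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicate class_id in reference library row ",
         which(duplicated(ids))[1], call. = FALSE)
  profiles <- as.matrix(raw[, -(1:2)])
  rownames(profiles) <- raw[[2]]
  new_reference_library(ids, raw[[2]], profiles, view)
}

#' Write a reference shape library to a text file
#'
#' @param library a `reference_library`.
#' @param path output path (tab-delimited, header line, 362 columns; names
#'   have spaces replaced by underscores so the file re-reads cleanly).
#' @return `path`, invisibly.
#' @export
write_reference_library <- function(library, path) {
  stopifnot(inherits(library, "reference_library"))
  df <- data.frame(class_id = library$class_id,
                   name = gsub(" ", "_", library$name),
                   library$profiles, check.names = FALSE)
  names(df)[-(1:2)] <- sprintf("deg%03d", 0:359)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify a polar profile against a reference library
#'
#' The candidate profile is mean-1 normalized and compared with every
#' reference outline by Pearson correlation of the 360-degree radius
#' vectors; the class with the highest correlation wins (ties resolve to
#' the lowest class_id). Profiles are assumed rotation-registered (side
#' views via [symmetrize()]); `register = "lag"` instead maximizes each
#' correlation over all 360 circular shifts.
#'
#' When exactly one of candidate and reference is constant the correlation
#' is undefined and reported as 0; when both are constant it is 1 if they
#' are equal after normalization (with a warning), else 0.
#'
#' @param profile a [to_polar()] result or numeric vector of 360 radii.
#' @param library a `reference_library`.
#' @param register `"none"` or `"lag"`.
#' @return Object of class `shape_classification`: list with `shape_class`
#'   (class_id), `class_name`, `corr` (winning correlation) and
#'   `per_class_corr` (named vector).
#' @export
classify_shape <- function(profile, library = default_reference_library(),
                           register = c("none", "lag")) {
  register <- match.arg(register)
  r <- if (inherits(profile, "polar_profile")) profile$radius_deg else profile
  stopifnot(is.numeric(r), length(r) == 360L, all(is.finite(r)), all(r > 0))
  stopifnot(inherits(library, "reference_library"))
  cand <- r / mean(r)
  one_corr <- function(ref, cand) {
    sc <- stats::sd(cand); sr <- stats::sd(ref)
    if (sc == 0 && sr == 0) {
      warning("constant candidate and reference; correlation by equality")
      return(if (isTRUE(all.equal(cand, ref))) 1 else 0)
    }
    if (sc == 0 || sr == 0) return(0)
    stats::cor(cand, ref)
  }
  per_class <- apply(library$profiles, 1L, function(ref) {
    if (register == "none") return(one_corr(ref, cand))
    max(vapply(0:359, function(lag) {
      one_corr(ref, c(cand[(lag + 1):360], cand[seq_len(lag)]))
    }, numeric(1)))
  })
  names(per_class) <- library$name
  best <- which.max(per_class)  # first max = lowest class_id on ties
  structure(list(shape_class = library$class_id[best],
                 class_name = library$name[best],
                 corr = unname(per_class[best]),
                 per_class_corr = per_class),
            class = "shape_classification")
}

#' Per-degree average of a set of polar profiles
#'
#' @param profiles matrix with one row per fruit and 360 columns (radii,
#'   typically in cm), or a list of [to_polar()] results or numeric
#'   vectors of equal view.
#' @return Object of class `average_shape`: list with `mean_radius_deg`,
#'   `sd_radius_deg` (sample SD; 0 when n = 1) and `n_fruit`.
#' @export
average_shape <- function(profiles) {
  if (is.list(profiles) && !is.data.frame(profiles)) {
    views <- unique(vapply(profiles, function(p) {
      if (inherits(p, "polar_profile")) p$view else NA_character_
    }, character(1)))
    views <- views[!is.na(views)]
    if (length(views) > 1L)
      stop("profiles mix views: ", paste(views, collapse = ", "),
           call. = FALSE)
    profiles <- do.call(rbind, lapply(profiles, function(p) {
      if (inherits(p, "polar_profile")) p$radius_deg else p
    }))
  }
  stopifnot(is.matrix(profiles), ncol(profiles) == 360L,
            nrow(profiles) >= 1L)
  n <- nrow(profiles)
  sdv <- if (n == 1L) rep(0, 360L) else apply(profiles, 2L, stats::sd)
  structure(list(mean_radius_deg = colMeans(profiles),
                 sd_radius_deg = sdv, n_fruit = n),
            class = "average_shape")
}

#' k-means clustering of shape profiles
#'
#' Clusters mean-1 normalized 360-degree profiles with k-means (Euclidean
#' distance, multiple random restarts). Labels are canonicalized by
#' ordering cluster centers lexicographically, so the labelling does not
#' depend on the input order of profiles.
#'
#' @param profiles matrix, one row per fruit, 360 columns.
#' @param k number of clusters (3 to 8; 6 by default).
#' @param cultivar optional per-row grouping; adds a cultivar x cluster
#'   count table to the result.
#' @param nstart random restarts for [stats::kmeans()].
#' @param seed RNG seed for the restarts.
#' @return List with `labels`, `centers` (k x 360), `withinss`,
#'   `tot_withinss` and (if `cultivar` given) `counts`.
#' @export
cluster_shapes <- function(profiles, k = 6L, cultivar = NULL,
                           nstart = 10L, seed = 1L) {
  stopifnot(is.matrix(profiles), ncol(profiles) == 360L)
  if (k < 1L || k > nrow(profiles))
    stop("k must be between 1 and the number of profiles", call. = FALSE)
  x <- profiles / rowMeans(profiles)
  if (k == nrow(x)) {
    km <- list(cluster = seq_len(k), centers = x,
               withinss = rep(0, k), tot.withinss = 0)
  } else {
    km <- with_seed(seed, stats::kmeans(x, centers = k, nstart = nstart,
                                        iter.max = 100L))
  }
  # canonical label order: lexicographic on the center vectors
  ord <- do.call(order, as.data.frame(km$centers))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labels <- relabel[km$cluster]
  out <- list(labels = labels,
              centers = km$centers[ord, , drop = FALSE],
              withinss = km$withinss[ord],
              tot_withinss = km$tot.withinss)
  if (!is.null(cultivar))
    out$counts <- table(cultivar = cultivar, cluster = labels)
  out
}
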