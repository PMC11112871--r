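#' Per-fruit hue and saturation histograms
#'
#' Pools the segmented fruit pixels of the four side views and builds
#' density histograms of hue and saturation over 64 uniform bins. Hue is
#' normalized to \[0, 1\] (= 0-360 degrees); pixels with zero saturation
#' (undefined hue) contribute to the saturation histogram only. Each
#' density integrates to 1. Plotting and factsheets restrict hue to
#' \[0, 0.5\] (yellow, red and green), but the full range is stored.
#'
#' @param images list of RGB arrays (typically the 4 side views).
#' @param masks list of logical matrices matching `images`.
#' @param bins number of histogram bins.
#' @return Object of class `color_histogram`: list with `hue_breaks` (65
#'   edges), `hue_density` (64 values), `sat_breaks`, `sat_density`,
#'   `n_pixels` (pooled pixel count) and `n_hue_pixels`.
#' @export
fruit_histogram <- function(images, masks, bins = 64L) {
  if (!is.list(images)) images <- list(images)
  if (!is.list(masks)) masks <- list(masks)
  if (length(images) != length(masks))
    stop("images and masks must pair up", call. = FALSE)
  hs <- lapply(seq_along(images), function(i) {
    assert_rgb(images[[i]])
    m <- masks[[i]]
    if (!identical(dim(images[[i]])[1:2], dim(m)))
      stop("mask ", i, " does not match its image", call. = FALSE)
    sel <- which(m > 0.5)
    if (!length(sel)) return(NULL)
    img <- images[[i]]
    n <- prod(dim(m))
    rgb <- rbind(img[sel], img[sel + n], img[sel + 2L * n])
    hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
    hsv[1:2, , drop = FALSE]
  })
  hs <- do.call(cbind, hs)
  if (is.null(hs) || ncol(hs) == 0L)
    stop("all masks are empty; no fruit pixels to analyze", call. = FALSE)
  h <- hs[1L, ]; s <- hs[2L, ]
  breaks <- seq(0, 1, length.out = bins + 1L)
  width <- 1 / bins
  dens <- function(x) {
    if (!length(x)) return(rep(0, bins))
    b <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
              bins)
    tabulate(b, nbins = bins) / (length(x) * width)
  }
  structure(list(hue_breaks = breaks, hue_density = dens(h[s > 0]),
                 sat_breaks = breaks, sat_density = dens(s),
                 n_pixels = length(s), n_hue_pixels = sum(s > 0)),
            class = "color_histogram")
}

#' Average color histogram across fruit
#'
#' Per-bin mean and sample standard deviation of the densities of several
#' fruit histograms with identical binning (e.g. all fruit of a cultivar).
#'
#' @param histograms list of [fruit_histogram()] results.
#' @return List with `hue_breaks`, `hue_mean`, `hue_sd`, `sat_mean`,
#'   `sat_sd`, `n_fruit`.
#' @export
cultivar_histogram <- function(histograms) {
  stopifnot(length(histograms) >= 1L)
  br <- histograms[[1L]]$hue_breaks
  for (h in histograms) {
    stopifnot(inherits(h, "color_histogram"))
    if (!isTRUE(all.equal(h$hue_breaks, br)))
      stop("histograms use different binning", call. = FALSE)
  }
  hm <- do.call(rbind, lapply(histograms, `[[`, "hue_density"))
  sm <- do.call(rbind, lapply(histograms, `[[`, "sat_density"))
  n <- nrow(hm)
  sdv <- function(m) if (n == 1L) rep(0, ncol(m)) else apply(m, 2L, stats::sd)
  list(hue_breaks = br, hue_mean = colMeans(hm), hue_sd = sdv(hm),
       sat_mean = colMeans(sm), sat_sd = sdv(sm), n_fruit = n)
}

# flat export column names for the per-fruit record table
colhist_header <- function(bins = 64L) {
  c(sprintf("hue_bin%02d", seq_len(bins)), sprintf("sat_bin%02d", seq_len(bins)))
}
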