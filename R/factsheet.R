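# One-page per-cultivar factsheet.

shape_panel <- function(shape) {
  deg <- 0:359
  th <- deg * pi / 180
  df <- data.frame(
    x = shape$mean_radius_deg * cos(th),
    y = shape$mean_radius_deg * sin(th),
    xlo = pmax(shape$mean_radius_deg - shape$sd_radius_deg, 0) * cos(th),
    ylo = pmax(shape$mean_radius_deg - shape$sd_radius_deg, 0) * sin(th),
    xhi = (shape$mean_radius_deg + shape$sd_radius_deg) * cos(th),
    yhi = (shape$mean_radius_deg + shape$sd_radius_deg) * sin(th))
  ggplot2::ggplot(df) +
    ggplot2::geom_path(ggplot2::aes(x = xlo, y = ylo), color = "grey70",
                       linewidth = 0.3) +
    ggplot2::geom_path(ggplot2::aes(x = xhi, y = yhi), color = "grey70",
                       linewidth = 0.3) +
    ggplot2::geom_path(ggplot2::aes(x = x, y = y), linewidth = 0.8) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("average side shape (n = %d)",
                                  shape$n_fruit),
                  x = "cm", y = "cm") +
    ggplot2::theme_minimal(base_size = 9)
}

hue_panel <- function(hist) {
  mid <- (hist$hue_breaks[-1] + hist$hue_breaks[-length(hist$hue_breaks)]) / 2
  keep <- mid <= 0.5  # yellow, red and green range shown on factsheets
  df <- data.frame(hue = mid[keep], mean = hist$hue_mean[keep],
                   sd = hist$hue_sd[keep])
  ggplot2::ggplot(df, ggplot2::aes(x = hue, y = mean)) +
    ggplot2::geom_col(fill = grDevices::hsv(df$hue, 0.85, 0.9),
                      width = diff(hist$hue_breaks)[1]) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(mean - sd, 0),
                                        ymax = mean + sd),
                           linewidth = 0.2, color = "grey40") +
    ggplot2::labs(title = "mean hue density (0-0.5)", x = "hue",
                  y = "density") +
    ggplot2::theme_minimal(base_size = 9)
}

table_lines <- function(traits) {
  c(sprintf("%-16s %8s %8s %8s %8s %8s", "trait", "mean",
            "median", "sd", "min", "max"),
    vapply(seq_len(nrow(traits)), function(i) {
      sprintf("%-16s %8.2f %8.2f %8.2f %8.2f %8.2f",
              traits$trait[i], traits$mean[i], traits$median[i],
              traits$sd[i], traits$min[i], traits$max[i])
    }, character(1)))
}

table_panel <- function(traits, cultivar, n_fruit) {
  lines <- table_lines(traits)
  ggplot2::ggplot() +
    ggplot2::annotate("text", x = 0, y = seq_along(lines), hjust = 0,
                      label = lines, family = "mono", size = 2.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(title = sprintf("%s  (n = %d fruit)", cultivar,
                                  n_fruit)) +
    ggplot2::theme_void(base_size = 9) +
    ggplot2::theme(plot.title = ggplot2::element_text(face = "bold"))
}

thumb_panel <- function(paths) {
  imgs <- lapply(paths, function(p) {
    if (is.null(p) || is.na(p) || !file.exists(p)) return(NULL)
    tiff::readTIFF(p)
  })
  n <- length(imgs)
  pl <- ggplot2::ggplot() +
    ggplot2::coord_fixed(xlim = c(0, n), ylim = c(0, 1), expand = FALSE) +
    ggplot2::theme_void()
  for (i in seq_len(n)) {
    if (is.null(imgs[[i]])) {
      pl <- pl + ggplot2::annotate("text", x = i - 0.5, y = 0.5,
                                   label = "missing", size = 2.5)
    } else {
      pl <- pl + ggplot2::annotation_raster(
        imgs[[i]], xmin = i - 0.98, xmax = i - 0.02, ymin = 0.05,
        ymax = 0.95)
    }
  }
  pl + ggplot2::labs(title = "first fruit, cameras 1-5") +
    ggplot2::theme(plot.title = ggplot2::element_text(size = 9))
}

#' Build a one-page cultivar factsheet
#'
#' Assembles a single-page PDF with the trait table, the average side
#' shape with its SD band, the mean hue histogram restricted to hue 0-0.5,
#' and thumbnails of the five views of the first fruit. Missing thumbnails
#' get a placeholder (with a warning). The layout is deterministic.
#'
#' @param summary a [summarize_cultivar()] result (with `shape` and
#'   `histogram` components).
#' @param image_paths character vector of up to 5 image paths of the first
#'   fruit, or NULL.
#' @param path output PDF path.
#' @return `path`, invisibly.
#' @export
make_factsheet <- function(summary, image_paths = NULL, path) {
  stopifnot(is.list(summary), !is.null(summary$traits))
  if (is.null(image_paths)) image_paths <- rep(NA_character_, 5L)
  if (!all(vapply(image_paths, function(p)
    !is.na(p) && file.exists(p), logical(1))))
    warning("missing thumbnails; placeholders used")
  panels <- list(table_panel(summary$traits, summary$cultivar,
                             summary$n_fruit))
  if (!is.null(summary$shape)) panels <- c(panels,
                                           list(shape_panel(summary$shape)))
  if (!is.null(summary$histogram))
    panels <- c(panels, list(hue_panel(summary$histogram)))
  panels <- c(panels, list(thumb_panel(image_paths)))
  page <- patchwork::wrap_plots(panels, ncol = 2)
  grDevices::pdf(path, width = 8.27, height = 11.69, onefile = TRUE)
  on.exit(grDevices::dev.off())
  print(page)
  invisible(path)
}
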