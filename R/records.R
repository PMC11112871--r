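# Per-fruit record assembly and per-cultivar statistics.

#' Analyze one fruit from its five views
#'
#' Runs the full single-fruit pipeline: segmentation of the four side views
#' and the top view against their background references, symmetry
#' correction and asymmetry of each side view, calibrated widths/heights,
#' top-view circle metrics, side-shape classification on the per-fruit
#' average side profile, top-shape classification, and the pooled hue /
#' saturation histogram.
#'
#' The per-fruit `asymmetry` is the mean of the four per-view minimal
#' asymmetry values; `shape_index` is mean height / mean width.
#'
#' @param images list of 5 RGB arrays (cameras 1-4 side, 5 top).
#' @param backgrounds list of 5 matching empty-box RGB arrays.
#' @param calibration cm-per-pixel per camera (length 1 or 5).
#' @param weight_g fruit mass in grams; `NA` is allowed and flagged.
#' @param sample_id,fruit_index identifiers carried into the record.
#' @param side_library,top_library reference libraries for classification.
#' @param bins color histogram bins.
#' @param symmetrize_range,symmetrize_step rotation search window passed to
#'   [symmetrize()].
#' @return Object of class `fruit_analysis`: list with `record` (one-row
#'   data frame, see [records_header()]), `side_profiles_cm` (4 x 360),
#'   `avg_side_profile_cm`, `top_profile` ([to_polar()] result),
#'   `classification`, `classification_top`, `histogram`, `masks`.
#' @export
build_fruit_record <- function(images, backgrounds, calibration, weight_g,
                               sample_id = "sample", fruit_index = 1L,
                               side_library = default_reference_library("side"),
                               top_library = default_reference_library("top"),
                               bins = 64L, symmetrize_range = 20,
                               symmetrize_step = 0.25) {
  if (length(images) != 5L || any(vapply(images, is.null, logical(1))))
    stop("need all 5 views; missing camera ",
         paste(which(vapply(images, is.null, logical(1))), collapse = ", "),
         call. = FALSE)
  if (length(backgrounds) != 5L)
    stop("need 5 background references", call. = FALSE)
  calibration <- rep_len(as.numeric(calibration), 5L)
  segs <- lapply(1:5, function(k) {
    segment_fruit(images[[k]], backgrounds[[k]],
                  image_id = sprintf("%s_cam%d_%d", sample_id, k,
                                     fruit_index))
  })
  widths <- heights <- asyms <- angles <- numeric(4L)
  side_prof_cm <- matrix(NA_real_, 4L, 360L)
  masks <- vector("list", 5L)
  for (k in 1:4) {
    sym <- symmetrize(segs[[k]]$mask, range_deg = symmetrize_range,
                      step_deg = symmetrize_step)
    d <- dimensions(sym$mask, calibration[k])
    widths[k] <- d[["width_cm"]]
    heights[k] <- d[["height_cm"]]
    asyms[k] <- sym$asymmetry
    angles[k] <- sym$symmetry_angle_deg
    side_prof_cm[k, ] <- to_polar(sym$mask, "side")$radius_deg *
      calibration[k]
    masks[[k]] <- sym$mask
  }
  masks[[5L]] <- segs[[5L]]$mask
  top_prof <- to_polar(segs[[5L]]$mask, "top")
  circ <- top_circles(top_prof)
  avg_side <- colMeans(side_prof_cm)
  cls <- classify_shape(avg_side, side_library)
  cls_top <- classify_shape(top_prof, top_library)
  hist <- fruit_histogram(images[1:4], lapply(segs[1:4], `[[`, "mask"),
                          bins = bins)
  rec <- data.frame(sample_id = sample_id, fruit_index = fruit_index,
                    ShapeClass = cls$shape_class, Corr_side = cls$corr,
                    ShapeClass_top = cls_top$shape_class,
                    weight_g = weight_g, weight_missing = is.na(weight_g),
                    radius_mean_pix = circ$radius_mean_px,
                    radius_in_pix = circ$radius_in_px,
                    radius_circ_pix = circ$radius_circ_px,
                    radius_std_nor_pix = circ$radius_std_nor,
                    stringsAsFactors = FALSE)
  rec[sprintf("width_cm_%d", 1:4)] <- as.list(widths)
  rec$width_mean_cm <- mean(widths)
  rec[sprintf("height_cm_%d", 1:4)] <- as.list(heights)
  rec$height_mean_cm <- mean(heights)
  rec$asymmetry <- mean(asyms)
  rec[sprintf("symmetry_angle_deg_%d", 1:4)] <- as.list(angles)
  rec$shape_index <- rec$height_mean_cm / rec$width_mean_cm
  rec[colhist_header(bins)] <- as.list(c(hist$hue_density,
                                         hist$sat_density))
  structure(list(record = rec, side_profiles_cm = side_prof_cm,
                 avg_side_profile_cm = avg_side, top_profile = top_prof,
                 classification = cls, classification_top = cls_top,
                 histogram = hist, masks = masks),
            class = "fruit_analysis")
}

#' Column names of the per-fruit record table
#'
#' @param bins color histogram bins used when the records were built.
#' @return Character vector of column names.
#' @export
records_header <- function(bins = 64L) {
  c("sample_id", "fruit_index", "ShapeClass", "Corr_side", "ShapeClass_top",
    "weight_g", "weight_missing", "radius_mean_pix", "radius_in_pix",
    "radius_circ_pix", "radius_std_nor_pix",
    sprintf("width_cm_%d", 1:4), "width_mean_cm",
    sprintf("height_cm_%d", 1:4), "height_mean_cm",
    "asymmetry", sprintf("symmetry_angle_deg_%d", 1:4), "shape_index",
    colhist_header(bins))
}

#' Write / read the per-fruit record table
#'
#' Tab-delimited text with a header; numeric values at 6 significant
#' digits.
#'
#' @param records data frame of per-fruit records.
#' @param path file path.
#' @return `read_records_table()` returns the data frame; the writer
#'   returns `path` invisibly.
#' @export
write_records_table <- function(records, path) {
  out <- records
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_records_table
#' @export
read_records_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

# compact letter display by insert-and-absorb from a logical "differs"
# matrix; groups are processed in name sort order
cld_letters <- function(differs) {
  g <- rownames(differs)
  g <- sort(g)
  differs <- differs[g, g, drop = FALSE]
  sets <- list(g)
  for (i in seq_along(g)) for (j in seq_len(i - 1L)) {
    if (!differs[i, j]) next
    hit <- vapply(sets, function(s) all(c(g[i], g[j]) %in% s), logical(1))
    if (!any(hit)) next
    new_sets <- list()
    for (s in sets[hit]) {
      new_sets <- c(new_sets, list(setdiff(s, g[i])), list(setdiff(s, g[j])))
    }
    sets <- c(sets[!hit], new_sets)
    # absorb: drop sets contained in another set, and duplicates
    keep <- rep(TRUE, length(sets))
    for (a in seq_along(sets)) for (b in seq_along(sets)) {
      if (a != b && keep[a] &&
          all(sets[[a]] %in% sets[[b]]) &&
          (length(sets[[a]]) < length(sets[[b]]) || a > b))
        keep[a] <- FALSE
    }
    sets <- sets[keep]
  }
  sets <- sets[order(vapply(sets, function(s) min(match(s, g)), numeric(1)))]
  letters_out <- setNames(rep("", length(g)), g)
  for (k in seq_along(sets)) {
    lab <- if (k <= 26) letters[k] else paste0(letters[(k - 1) %/% 26],
                                               letters[(k - 1) %% 26 + 1])
    for (m in sets[[k]]) letters_out[m] <- paste0(letters_out[m], lab)
  }
  letters_out
}

#' One-way ANOVA with Tukey HSD significance letters
#'
#' Fits a fixed-effects one-way ANOVA of a trait against a grouping factor,
#' runs Tukey's honest significant difference post hoc test, and summarizes
#' the pairwise results as a compact letter display (groups sharing a
#' letter do not differ at the chosen level).
#'
#' @param values numeric trait values.
#' @param group grouping factor (e.g. cultivar), >= 2 levels with >= 2
#'   observations each.
#' @param alpha significance level for the letter display.
#' @return List with `f_value`, `p_value`, `p_label` (`"<2e-16"` when
#'   below that floor), `tukey` (matrix of adjusted pairwise p-values),
#'   and `letters` (named by group).
#' @export
significance_groups <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 2L)
    stop("need at least two groups", call. = FALSE)
  tab <- table(group)
  if (any(tab < 2L))
    stop("groups with fewer than 2 observations: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  df <- data.frame(y = values, g = group)
  fit <- stats::aov(y ~ g, data = df)
  an <- stats::anova(fit)
  p <- an[["Pr(>F)"]][1L]
  tk <- stats::TukeyHSD(fit, "g")$g
  lev <- levels(group)
  pmat <- matrix(1, nlevels(group), nlevels(group),
                 dimnames = list(lev, lev))
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pair)) {
    a <- pair[[i]][1L]; b <- pair[[i]][2L]
    pmat[a, b] <- pmat[b, a] <- tk[i, "p adj"]
  }
  letters_out <- cld_letters(pmat < alpha)
  list(f_value = an[["F value"]][1L], p_value = p,
       p_label = if (p < 2e-16) "<2e-16" else format(p, digits = 3),
       tukey = pmat, letters = letters_out[lev])
}

#' Trait summary across cultivars with significance letters
#'
#' Descriptive statistics (n, mean, median, SD, min, max) per cultivar and
#' trait, plus one-way ANOVA p-values and Tukey letters per trait.
#'
#' @param records data frame with a `cultivar` column and the trait
#'   columns.
#' @param traits trait column names to summarize.
#' @param alpha significance level for the letters.
#' @return List with `summary` (long data frame: cultivar, trait, n, mean,
#'   median, sd, min, max, letter) and `anova` (trait, f_value, p_value,
#'   p_label).
#' @export
trait_summary <- function(records,
                          traits = c("height_mean_cm", "width_mean_cm",
                                     "weight_g", "shape_index",
                                     "asymmetry"),
                          alpha = 0.05) {
  stopifnot("cultivar" %in% names(records))
  traits <- intersect(traits, names(records))
  rows <- list(); anova_rows <- list()
  for (tr in traits) {
    v <- records[[tr]]; g <- factor(records$cultivar)
    ok <- is.finite(v)
    sig <- tryCatch(significance_groups(v[ok], g[ok], alpha = alpha),
                    error = function(e) NULL)
    per <- do.call(rbind, lapply(levels(g), function(cv) {
      x <- v[ok & g == cv]
      data.frame(cultivar = cv, trait = tr, n = length(x),
                 mean = mean(x), median = stats::median(x),
                 sd = if (length(x) > 1L) stats::sd(x) else 0,
                 min = if (length(x)) min(x) else NA_real_,
                 max = if (length(x)) max(x) else NA_real_,
                 letter = if (is.null(sig)) NA_character_
                          else unname(sig$letters[cv]))
    }))
    rows[[tr]] <- per
    anova_rows[[tr]] <- data.frame(
      trait = tr,
      f_value = if (is.null(sig)) NA_real_ else sig$f_value,
      p_value = if (is.null(sig)) NA_real_ else sig$p_value,
      p_label = if (is.null(sig)) NA_character_ else sig$p_label)
  }
  list(summary = do.call(rbind, rows), anova = do.call(rbind, anova_rows))
}

#' Summarize one cultivar
#'
#' Descriptive trait statistics, the average side shape with angle-specific
#' SD, and the mean color histogram for the fruit of one cultivar.
#'
#' @param records per-fruit records of one cultivar.
#' @param side_profiles_cm optional matrix (one row per fruit, 360 columns)
#'   of per-fruit average side profiles in cm.
#' @param histograms optional list of [fruit_histogram()] results.
#' @param cultivar label stored on the output.
#' @return List with `cultivar`, `n_fruit`, `traits` (data frame), `shape`
#'   ([average_shape()] or NULL) and `histogram`
#'   ([cultivar_histogram()] or NULL).
#' @export
summarize_cultivar <- function(records, side_profiles_cm = NULL,
                               histograms = NULL, cultivar = NULL) {
  stopifnot(nrow(records) >= 1L)
  traits <- intersect(c("height_mean_cm", "width_mean_cm", "weight_g",
                        "shape_index", "asymmetry"), names(records))
  tr <- do.call(rbind, lapply(traits, function(t) {
    x <- records[[t]]; x <- x[is.finite(x)]
    data.frame(trait = t, n = length(x), mean = mean(x),
               median = stats::median(x),
               sd = if (length(x) > 1L) stats::sd(x) else 0,
               min = min(x), max = max(x))
  }))
  list(cultivar = cultivar %||% records$sample_id[1L],
       n_fruit = nrow(records), traits = tr,
       shape = if (!is.null(side_profiles_cm))
         average_shape(side_profiles_cm) else NULL,
       histogram = if (!is.null(histograms))
         cultivar_histogram(histograms) else NULL)
}
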