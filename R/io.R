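# Acquisition directory dialect and batch extraction.
#
# Layout: root/images/<ID>/cam<N>/<ID>_cam<N>_<index>_<YYYYMMDD>_<HHMMSS>.tif
# with a zero-padded 4-digit index, plus root/background/cam<N>.tif empty-box
# references. The fruit weight travels in the TIFF description field
# ("weight_g=<decimal>") when the writer supports it, with a per-directory
# manifest.tsv (filename, weight_g) as sidecar; on read the description
# field wins over the manifest.

.filename_pattern <-
  "^(.+)_cam([0-9])_([0-9]+)_([0-9]{8})_([0-9]{6})\\.tiff?$"

#' Compose / parse acquisition image filenames
#'
#' The default dialect is `<ID>_cam<N>_<index>_<YYYYMMDD>_<HHMMSS>.tif`
#' with a 4-digit zero-padded index; `parse_fruit_filename()` accepts any
#' index width and, via `pattern`, other dialects with the same five
#' capture groups (id, camera, index, date, time).
#'
#' @param id sample identifier (barcode text).
#' @param camera camera number 1-5.
#' @param index fruit index >= 1.
#' @param timestamp a POSIXct.
#' @return `fruit_filename()`: the file name. `parse_fruit_filename()`: a
#'   one-row data frame (`id`, `camera`, `fruit_index`, `date`, `time`),
#'   or `NULL` when the name does not match.
#' @export
fruit_filename <- function(id, camera, index, timestamp) {
  sprintf("%s_cam%d_%04d_%s_%s.tif", id, as.integer(camera),
          as.integer(index), format(timestamp, "%Y%m%d"),
          format(timestamp, "%H%M%S"))
}

#' @rdname fruit_filename
#' @param name a file name (no directory part).
#' @param pattern regular expression with the five capture groups.
#' @export
parse_fruit_filename <- function(name, pattern = .filename_pattern) {
  m <- regmatches(name, regexec(pattern, name))[[1L]]
  if (length(m) != 6L) return(NULL)
  data.frame(id = m[2L], camera = as.integer(m[3L]),
             fruit_index = as.integer(m[4L]), date = m[5L], time = m[6L],
             stringsAsFactors = FALSE)
}

manifest_path <- function(image_path) {
  file.path(dirname(image_path), "manifest.tsv")
}

update_manifest <- function(image_path, weight_g) {
  mp <- manifest_path(image_path)
  fn <- basename(image_path)
  df <- if (file.exists(mp))
    utils::read.delim(mp, stringsAsFactors = FALSE)
  else data.frame(filename = character(), weight_g = character(),
                  stringsAsFactors = FALSE)
  df$weight_g <- as.character(df$weight_g)
  df <- df[df$filename != fn, , drop = FALSE]
  df <- rbind(df, data.frame(filename = fn,
                             weight_g = format(weight_g, digits = 15),
                             stringsAsFactors = FALSE))
  utils::write.table(df, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mp)
}

#' Write a fruit image as 16-bit packbits TIFF
#'
#' Values are quantized to the 16-bit grid (see [quantize16()]) and
#' encoded so that read-back is bit-identical to the quantized array. A
#' non-missing `weight_g` is recorded in the directory's `manifest.tsv`
#' sidecar.
#'
#' @param image RGB array in \[0, 1\].
#' @param path output path.
#' @param weight_g optional fruit mass in grams.
#' @return `path`, invisibly.
#' @export
write_fruit_image <- function(image, path, weight_g = NULL) {
  assert_rgb(image)
  k <- round(pmin(pmax(image, 0), 1) * 65535)
  enc <- pmin((k + 0.5) / 65535, 1)  # writeTIFF truncates; encode mid-bin
  tiff::writeTIFF(enc, path, bits.per.sample = 16L,
                  compression = "PackBits")
  if (!is.null(weight_g) && !is.na(weight_g))
    update_manifest(path, weight_g)
  invisible(path)
}

#' Read a fruit image and its weight
#'
#' Reads a TIFF into an RGB array in \[0, 1\] and recovers the fruit
#' weight: a `weight_g=<decimal>` entry in the TIFF description field
#' takes precedence; otherwise the directory's `manifest.tsv` is
#' consulted. A missing weight is returned as `NA` (flagged, not an
#' error).
#'
#' @param path TIFF path.
#' @return List with `image`, `weight_g`, `weight_source`
#'   (`"metadata"`, `"manifest"` or `NA`) and `info` (TIFF attributes).
#' @export
read_image_with_weight <- function(path) {
  if (!file.exists(path)) stop("no such image: ", path, call. = FALSE)
  img <- tryCatch(tiff::readTIFF(path, info = TRUE),
                  error = function(e)
                    stop("unreadable TIFF '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  info <- attributes(img)
  w_meta <- NA_real_
  desc <- info$description
  if (!is.null(desc)) {
    m <- regmatches(desc, regexec("weight_g=([0-9.eE+-]+)", desc))[[1L]]
    if (length(m) == 2L) w_meta <- as.numeric(m[2L])
  }
  w_man <- NA_real_
  mp <- manifest_path(path)
  if (file.exists(mp)) {
    man <- utils::read.delim(mp, stringsAsFactors = FALSE)
    hit <- match(basename(path), man$filename)
    if (!is.na(hit)) w_man <- as.numeric(man$weight_g[hit])
  }
  if (!is.na(w_meta) && !is.na(w_man) && w_meta != w_man)
    warning("weight in metadata (", w_meta, ") and manifest (", w_man,
            ") disagree for ", basename(path), "; using metadata")
  weight <- if (!is.na(w_meta)) w_meta else w_man
  source <- if (!is.na(w_meta)) "metadata"
            else if (!is.na(w_man)) "manifest" else NA_character_
  dim3 <- dim(img)
  if (length(dim3) == 2L) img <- array(rep(img, 3L), c(dim3, 3L))
  list(image = img[, , 1:3, drop = FALSE], weight_g = weight,
       weight_source = source, info = info)
}

#' Scan an acquisition directory for complete fruit
#'
#' Walks `root/images/<ID>/cam<N>/`, parses every file name, and groups
#' images by (ID, fruit index). A fruit is complete when all five cameras
#' contributed exactly one image. Unparseable names, incomplete fruit and
#' duplicate (ID, camera, index) combinations are reported as anomalies,
#' never as errors.
#'
#' @param root acquisition root containing an `images/` directory.
#' @param pattern filename dialect (see [parse_fruit_filename()]).
#' @return List with `fruits` (data frame: `id`, `fruit_index`,
#'   `path_cam1` ... `path_cam5`) and `anomalies` (list with
#'   `unparseable`, `incomplete`, `duplicates`).
#' @export
scan_acquisitions <- function(root, pattern = .filename_pattern) {
  imgroot <- file.path(root, "images")
  if (!dir.exists(imgroot))
    stop("no images/ directory under ", root, call. = FALSE)
  files <- list.files(imgroot, recursive = TRUE, full.names = TRUE)
  files <- files[grepl("\\.tiff?$", files, ignore.case = TRUE)]
  parsed <- lapply(basename(files), parse_fruit_filename, pattern = pattern)
  ok <- !vapply(parsed, is.null, logical(1))
  unparseable <- files[!ok]
  meta <- do.call(rbind, parsed[ok])
  if (is.null(meta) || nrow(meta) == 0L)
    return(list(fruits = data.frame(), anomalies =
                  list(unparseable = unparseable,
                       incomplete = data.frame(), duplicates = character())))
  meta$path <- files[ok]
  key <- paste(meta$id, meta$camera, meta$fruit_index)
  duplicates <- meta$path[duplicated(key) | duplicated(key, fromLast = TRUE)]
  meta <- meta[!duplicated(key), , drop = FALSE]
  fruits <- list(); incomplete <- list()
  for (grp in split(meta, paste(meta$id, meta$fruit_index))) {
    cams <- sort(grp$camera)
    if (identical(cams, 1:5)) {
      row <- data.frame(id = grp$id[1L], fruit_index = grp$fruit_index[1L],
                        stringsAsFactors = FALSE)
      for (k in 1:5)
        row[[sprintf("path_cam%d", k)]] <- grp$path[grp$camera == k]
      fruits[[length(fruits) + 1L]] <- row
    } else {
      incomplete[[length(incomplete) + 1L]] <-
        data.frame(id = grp$id[1L], fruit_index = grp$fruit_index[1L],
                   missing_cameras = paste(setdiff(1:5, cams),
                                           collapse = ","),
                   stringsAsFactors = FALSE)
    }
  }
  fruits <- if (length(fruits)) do.call(rbind, fruits) else data.frame()
  if (nrow(fruits))
    fruits <- fruits[order(fruits$id, fruits$fruit_index), , drop = FALSE]
  list(fruits = fruits,
       anomalies = list(
         unparseable = unparseable,
         incomplete = if (length(incomplete)) do.call(rbind, incomplete)
                      else data.frame(),
         duplicates = duplicates))
}

#' Read a field plan
#'
#' Tab-delimited text with header columns `tree_id`, `cultivar`, `row`,
#' `position`; `tree_id` must be unique.
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_field_plan <- function(path) {
  fp <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tree_id", "cultivar", "row", "position")
  if (!all(need %in% names(fp)))
    stop("field plan must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(fp$tree_id))
    stop("duplicate tree_id in field plan: ",
         fp$tree_id[duplicated(fp$tree_id)][1L], call. = FALSE)
  fp
}

#' Read / write a per-camera calibration file
#'
#' Plain key = value text, one line per camera (`cam1 = 0.01`), values in
#' cm per pixel.
#'
#' @param path file path.
#' @return Named numeric vector of length 5 (cam1..cam5).
#' @export
read_calibration <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  cal <- setNames(rep(NA_real_, 5L), sprintf("cam%d", 1:5))
  cal[keys] <- vals
  if (anyNA(cal) || any(cal <= 0))
    stop("calibration must give a positive cm-per-px value for each of ",
         "cam1..cam5", call. = FALSE)
  cal
}

#' @rdname read_calibration
#' @param calibration numeric vector of 5 positive cm-per-px values.
#' @export
write_calibration <- function(calibration, path) {
  calibration <- rep_len(as.numeric(calibration), 5L)
  writeLines(sprintf("cam%d = %.10g", 1:5, calibration), path)
  invisible(path)
}

#' Run the full extraction pipeline over an acquisition directory
#'
#' Scans `root`, analyzes every complete fruit ([build_fruit_record()]),
#' joins cultivar names from the field plan (IDs without a plan entry keep
#' their ID as cultivar), and optionally writes per-cultivar record tables
#' plus the standard text exports (average side shape in polar and
#' Cartesian coordinates, raw color histograms, reference-shape
#' correlations, weight and caliber). Per-fruit failures are logged and
#' skipped.
#'
#' @param root acquisition root (see [scan_acquisitions()]).
#' @param calibration numeric vector of 5 cm-per-px values, or a path to a
#'   calibration file.
#' @param field_plan data frame from [read_field_plan()], a path, or NULL.
#' @param out_dir output directory for text exports; NULL skips writing.
#' @param ... passed to [build_fruit_record()].
#' @return List with `records` (data frame incl. `cultivar`),
#'   `side_profiles_cm` (matrix, one row per fruit), `histograms`,
#'   `classifications`, `log` (per-fruit status data frame), `anomalies`,
#'   and `paths` of written exports.
#' @export
run_extract <- function(root, calibration, field_plan = NULL,
                        out_dir = NULL, ...) {
  if (is.character(calibration) && length(calibration) == 1L &&
      file.exists(calibration))
    calibration <- read_calibration(calibration)
  calibration <- rep_len(as.numeric(calibration), 5L)
  if (is.character(field_plan)) field_plan <- read_field_plan(field_plan)
  scan <- scan_acquisitions(root)
  if (!nrow(scan$fruits)) stop("no complete fruit found under ", root,
                               call. = FALSE)
  backgrounds <- lapply(1:5, function(k) {
    bp <- file.path(root, "background", sprintf("cam%d.tif", k))
    if (!file.exists(bp))
      stop("missing background reference ", bp, call. = FALSE)
    read_image_with_weight(bp)$image
  })
  records <- list(); profs <- list(); hists <- list(); clss <- list()
  log <- list()
  for (i in seq_len(nrow(scan$fruits))) {
    row <- scan$fruits[i, ]
    res <- tryCatch({
      views <- lapply(1:5, function(k)
        read_image_with_weight(row[[sprintf("path_cam%d", k)]]))
      weights <- vapply(views, `[[`, numeric(1), "weight_g")
      weight <- if (all(is.na(weights))) NA_real_
                else weights[which(!is.na(weights))[1L]]
      build_fruit_record(lapply(views, `[[`, "image"), backgrounds,
                         calibration, weight, sample_id = row$id,
                         fruit_index = row$fruit_index, ...)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log[[i]] <- data.frame(id = row$id, fruit_index = row$fruit_index,
                             status = "failed",
                             message = conditionMessage(res))
      next
    }
    log[[i]] <- data.frame(id = row$id, fruit_index = row$fruit_index,
                           status = "ok", message = "")
    records[[length(records) + 1L]] <- res$record
    profs[[length(profs) + 1L]] <- res$avg_side_profile_cm
    hists[[length(hists) + 1L]] <- res$histogram
    clss[[length(clss) + 1L]] <- res$classification
  }
  if (!length(records))
    stop("all fruit failed; see the returned log", call. = FALSE)
  records <- do.call(rbind, records)
  side_profiles <- do.call(rbind, profs)
  cultivar <- records$sample_id
  if (!is.null(field_plan)) {
    hit <- match(records$sample_id, field_plan$tree_id)
    cultivar[!is.na(hit)] <- field_plan$cultivar[hit[!is.na(hit)]]
  }
  records$cultivar <- cultivar
  out <- list(records = records, side_profiles_cm = side_profiles,
              histograms = hists, classifications = clss,
              log = do.call(rbind, log), anomalies = scan$anomalies,
              paths = character())
  if (!is.null(out_dir)) out$paths <- write_extract_outputs(out, out_dir)
  out
}

# standard text exports of an extraction result
write_extract_outputs <- function(extract, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  recs <- extract$records
  for (cv in sort(unique(recs$cultivar))) {
    sel <- recs$cultivar == cv
    safe <- gsub("[^A-Za-z0-9_.-]", "_", cv)
    p <- file.path(out_dir, paste0(safe, "_records.tsv"))
    write_records_table(recs[sel, , drop = FALSE], p)
    paths <- c(paths, p)
    avg <- average_shape(extract$side_profiles_cm[sel, , drop = FALSE])
    deg <- 0:359
    shp <- data.frame(degree = deg,
                      radius_mean_cm = avg$mean_radius_deg,
                      radius_sd_cm = avg$sd_radius_deg,
                      x_cm = avg$mean_radius_deg * cos(deg * pi / 180),
                      y_cm = avg$mean_radius_deg * sin(deg * pi / 180))
    p <- file.path(out_dir, paste0(safe, "_avg_shape.tsv"))
    utils::write.table(format(shp, digits = 6, trim = TRUE), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  # raw histograms, one row per fruit
  hist_cols <- recs[, c("sample_id", "fruit_index", "cultivar",
                        colhist_header()), drop = FALSE]
  p <- file.path(out_dir, "color_histograms.tsv")
  write_records_table(hist_cols, p); paths <- c(paths, p)
  # correlations to the reference shapes
  corr <- do.call(rbind, lapply(extract$classifications, function(cl)
    as.data.frame(as.list(cl$per_class_corr), check.names = FALSE)))
  corr <- cbind(recs[, c("sample_id", "fruit_index", "cultivar")], corr)
  p <- file.path(out_dir, "shape_correlations.tsv")
  write_records_table(corr, p); paths <- c(paths, p)
  # weight and caliber (width as the commercial size measure)
  wc <- recs[, c("sample_id", "fruit_index", "cultivar", "weight_g",
                 "width_mean_cm", "height_mean_cm", "shape_index")]
  p <- file.path(out_dir, "weight_caliber.tsv")
  write_records_table(wc, p); paths <- c(paths, p)
  paths
}
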