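#' Read an image file as an [H, W, C] array in [0, 1]
#'
#' PNG via the png package, other formats (JPEG/TIFF) via EBImage.
#' Grayscale images gain a singleton channel dim.
#'
#' @param path Image file path.
#' @return `[H, W, C]` double array with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
  } else {
    img <- EBImage::readImage(path)
    a <- as.array(img)
    a <- if (length(dim(a)) == 2) t(a) else aperm(a, c(2, 1, 3))
  }
  if (length(dim(a)) == 2) dim(a) <- c(dim(a), 1L)
  if (dim(a)[3] == 4) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  a[a < 0] <- 0; a[a > 1] <- 1
  a
}

#' Parse capture timestamps from frame filenames
#'
#' Looks for a `YYYYmmdd_HHMM` token in each basename (the naming used by
#' [generate_growth_series()] when writing frames).
#'
#' @param paths Character vector of file paths.
#' @return POSIXct vector (UTC); `NA` where no token is found.
#' @export
parse_frame_times <- function(paths) {
  out <- rep(as.POSIXct(NA), length(paths))
  tok <- regexpr("[0-9]{8}_[0-9]{4}", basename(paths))
  found <- tok > 0
  out[found] <- as.POSIXct(regmatches(basename(paths), tok),
                           format = "%Y%m%d_%H%M", tz = "UTC")
  out
}

.io_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cropseg_error")))
}

#' Read a labelme-style polygon annotation
#'
#' Loads the referenced image (normalized to `[0, 1]`) and rasterizes the
#' first polygon shape (or the first one whose label matches `label`) into
#' the ground-truth mask of the central object.
#'
#' @param json_path Path to the annotation JSON.
#' @param label Optional shape label to select; default = first polygon.
#' @return `list(image, mask, label)` (an annotated sample).
#' @section Errors: malformed JSON signals `cropseg_bad_json`; a document
#'   without polygon shapes signals `cropseg_no_annotation`; a missing
#'   image file signals `cropseg_missing_image`.
#' @export
read_annotation <- function(json_path, label = NULL) {
  doc <- tryCatch(jsonlite::fromJSON(json_path, simplifyVector = FALSE),
                  error = function(e)
                    .io_error(paste("malformed annotation JSON:",
                                    conditionMessage(e)), "cropseg_bad_json"))
  shapes <- doc$shapes
  is_poly <- vapply(shapes, function(s)
    is.null(s$shape_type) || identical(s$shape_type, "polygon"), TRUE)
  if (!is.null(label))
    is_poly <- is_poly & vapply(shapes, function(s)
      identical(s$label, label), TRUE)
  if (length(shapes) == 0 || !any(is_poly))
    .io_error("annotation contains no polygon shape", "cropseg_no_annotation")
  shape <- shapes[[which(is_poly)[1]]]
  if (is.null(doc$imagePath))
    .io_error("annotation has no image reference", "cropseg_missing_image")
  img_path <- file.path(dirname(json_path), doc$imagePath)
  if (!file.exists(img_path))
    .io_error(sprintf("referenced image not found: %s", img_path),
              "cropseg_missing_image")
  image <- read_image(img_path)
  verts <- do.call(rbind, lapply(shape$points, unlist))
  mask <- rasterize_polygon(verts, dim(image)[1:2])
  list(image = image, mask = mask,
       label = if (is.null(shape$label)) NA_character_ else shape$label)
}

#' Write a synthetic scene as PNG + labelme-style JSON
#'
#' The mask boundary is stored as a dense polygon approximation, so the
#' annotation round-trips through [read_annotation()] with only
#' polygonization loss.
#'
#' @param scene A [generate_scene()] result.
#' @param dir Output directory.
#' @param name Basename (without extension).
#' @return Path of the JSON file, invisibly.
#' @export
write_scene_annotation <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_file <- paste0(name, ".png")
  png::writePNG(scene$image, file.path(dir, img_file))
  doc <- list(
    version = "5.0.0",
    flags = structure(list(), names = character(0)),
    shapes = list(list(label = "central_object",
                       points = lapply(seq_len(nrow(scene$polygon)),
                                       function(i) as.numeric(scene$polygon[i, ])),
                       shape_type = "polygon")),
    imagePath = img_file,
    imageHeight = dim(scene$image)[1],
    imageWidth = dim(scene$image)[2])
  path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write tracking outputs: measurements CSV, mask PNGs, fit CSV, manifest
#'
#' Writes `measurements.csv` (one row per record: frame id, ISO-8601
#' timestamp, the 11 per-scale areas, median, CV, centre, chosen scale,
#' flags), one 8-bit PNG mask per record (`0` background / `255`
#' foreground), optionally `fitted_curve.csv` (time, fitted area), and a
#' JSON manifest listing every written file with its MD5 checksum.
#'
#' @param series A `growth_series`.
#' @param out_dir Output directory (must be creatable/writable; checked
#'   before anything is written).
#' @param fit Optional [fit_growth_curve()] result.
#' @return The manifest (named list), invisibly.
#' @export
write_outputs <- function(series, out_dir, fit = NULL) {
  stopifnot(inherits(series, "growth_series"))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    stop(sprintf("output directory not writable: %s", out_dir))
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  r <- series$records
  csv <- r
  csv$timestamp <- format(csv$timestamp, "%Y-%m-%dT%H:%M:%S")
  meas_path <- file.path(out_dir, "measurements.csv")
  utils::write.csv(csv, meas_path, row.names = FALSE)
  files <- meas_path
  for (i in seq_len(nrow(r))) {
    p <- file.path(out_dir, "masks",
                   sprintf("mask_%04d.png", r$frame_id[i]))
    png::writePNG(series$masks[[i]], p)
    files <- c(files, p)
  }
  if (!is.null(fit)) {
    fp <- file.path(out_dir, "fitted_curve.csv")
    utils::write.csv(data.frame(time_hours = fit$time_hours,
                                fitted_area = fit$fitted),
                     fp, row.names = FALSE)
    files <- c(files, fp)
  }
  manifest <- list(files = lapply(files, function(f)
    list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Read tracking measurements back from CSV
#'
#' Inverse of the measurements table written by [write_outputs()];
#' numeric values round-trip to within 1e-9.
#'
#' @param path Path to `measurements.csv`.
#' @return A data frame with POSIXct timestamps.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path)
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                             tz = "UTC")
  df
}

#' Read / write a YAML run configuration
#'
#' A flat-or-nested key-value config mirroring the constructors'
#' arguments (`network`, `protocol`, `augment`, `scene`, `growth`,
#' `tracking`, `seed`); used by the command-line interface in
#' `inst/cli/cropseg.R`.
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @param config Named list to serialize.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
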