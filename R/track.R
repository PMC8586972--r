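#' Initialize a track from a rough manual selection
#'
#' The user marks the target object with a rough box on the first frame;
#' tracking starts from the box centre with a base measurement window of
#' side `round(margin * max(w, h))` pixels (windows are clamped to the
#' frame when used).
#'
#' @param frame The first frame (`[H, W, C]` array), used for bounds.
#' @param manual_box `c(x, y, w, h)`: top-left corner and size in pixels,
#'   0-based from the top-left of the frame.
#' @param margin Window margin factor (default 2.0).
#' @return An object of class `track_state` with fields `center` (x, y)
#'   and `w0`.
#' @export
init_track <- function(frame, manual_box, margin = 2.0) {
  d <- dim(frame)
  x <- manual_box[1]; y <- manual_box[2]
  w <- manual_box[3]; h <- manual_box[4]
  if (w <= 0 || h <= 0) stop("manual box must have positive width and height")
  if (x < 0 || y < 0 || x + w > d[2] || y + h > d[1])
    stop("manual box must lie inside the frame")
  structure(list(center = c(x = x + w / 2, y = y + h / 2),
                 w0 = round(margin * max(w, h)),
                 frame_dim = d[1:2]),
            class = "track_state")
}

#' The 11-step measurement scale ladder
#'
#' Factors 1.00, 0.95, ..., 0.50 (inclusive, uniform step 0.05) applied to
#' the base window side: the same object is measured at 11 zoom levels and
#' the median of the rescaled areas is kept.
#'
#' @return A numeric vector of length 11.
#' @export
scale_ladder <- function() seq(100L, 50L, by = -5L) / 100

#' Wrap a trained network as a tracking segmenter
#'
#' The returned function takes a square crop (already resized to the
#' network's input side) plus a window-geometry request and returns the
#' test-time-augmented binary mask.
#'
#' @param network A trained `crop_network`.
#' @param threshold Binarization threshold.
#' @return A `function(image, request)` with attribute `input_side`.
#' @export
make_network_segmenter <- function(network, threshold = 0.5) {
  stopifnot(inherits(network, "crop_network"))
  fn <- function(image, request) tta_segment(network, image, threshold)$mask
  attr(fn, "input_side") <- network$config$input_side
  fn
}

.area_cols <- function() sprintf("area_scale_%03d", round(scale_ladder() * 100))

#' Multi-scale median measurement of the tracked object in one frame
#'
#' For each factor `s` of the [scale_ladder()], a square window of side
#' `round(s * w0)` centred on the current track centre (clamped to the
#' frame) is cropped, resized to the segmenter's input side `P`, and
#' segmented; the mask pixel count `n` is rescaled to full-frame units as
#' `a = n * (side / P)^2` (in general fractional).  The median of the 11
#' rescaled areas is kept, together with the mask attaining it (smallest
#' scale index on ties), the 2D centre of mass of that mask mapped back to
#' full-frame coordinates, and the coefficient of variation (population
#' standard deviation / mean) of the 11 areas.  An empty chosen mask keeps
#' the previous centre and raises the `empty` flag; a zero mean leaves the
#' CV undefined (`NA`).
#'
#' @param segmenter A segmenter function ([make_network_segmenter()] or
#'   [make_oracle_segmenter()]).
#' @param frame `[H, W, C]` image.
#' @param state A [init_track()] state.
#' @param frame_id,timestamp Identifiers stored in the record.
#' @return `list(record, mask, center)`; `record` is a one-row data frame
#'   with the 11 per-scale areas, `median_area_px`, `cv`, `center_x`,
#'   `center_y`, `chosen_scale`, `empty`.
#' @export
multiscale_measure <- function(segmenter, frame, state, frame_id = 1L,
                               timestamp = as.POSIXct(NA)) {
  stopifnot(inherits(state, "track_state"))
  P <- attr(segmenter, "input_side")
  if (is.null(P)) stop("segmenter must carry an input_side attribute")
  d <- dim(frame)
  H <- d[1]; W <- d[2]
  cx <- state$center[["x"]]; cy <- state$center[["y"]]
  factors <- scale_ladder()
  areas <- numeric(11)
  masks <- vector("list", 11)
  geoms <- vector("list", 11)
  for (i in seq_along(factors)) {
    wi <- round(factors[i] * state$w0)
    wi <- max(2L, min(wi, H, W))
    x0 <- min(max(0, round(cx - wi / 2)), W - wi)
    y0 <- min(max(0, round(cy - wi / 2)), H - wi)
    crop <- frame[y0 + seq_len(wi), x0 + seq_len(wi), , drop = FALSE]
    if (wi != P) crop <- resize_raster(crop, P, P, "bilinear")
    crop[crop < 0] <- 0; crop[crop > 1] <- 1
    msk <- segmenter(crop, list(frame = frame_id, x0 = x0, y0 = y0,
                                side = wi, out = P))
    masks[[i]] <- msk
    geoms[[i]] <- c(x0 = x0, y0 = y0, side = wi)
    areas[i] <- sum(msk) * (wi / P)^2
  }
  med <- sort(areas)[6]
  chosen <- which(areas == med)[1]
  cmask <- masks[[chosen]]
  g <- geoms[[chosen]]
  empty <- sum(cmask) == 0
  if (empty) {
    center <- c(x = cx, y = cy)
  } else {
    idx <- which(cmask == 1, arr.ind = TRUE)
    sc <- g[["side"]] / P
    center <- c(x = g[["x0"]] + mean(idx[, 2] - 0.5) * sc,
                y = g[["y0"]] + mean(idx[, 1] - 0.5) * sc)
  }
  mu <- mean(areas)
  cv <- if (mu == 0) NA_real_ else sqrt(mean((areas - mu)^2)) / mu
  rec <- data.frame(frame_id = frame_id, timestamp = timestamp)
  rec[.area_cols()] <- as.list(areas)
  rec$median_area_px <- med
  rec$cv <- cv
  rec$center_x <- center[["x"]]
  rec$center_y <- center[["y"]]
  rec$chosen_scale <- factors[chosen]
  rec$empty <- empty
  rec$outlier_flag <- FALSE
  rec$replaced_from <- NA_integer_
  list(record = rec, mask = cmask, center = center)
}

#' Track an object through a time-ordered image series
#'
#' Applies [multiscale_measure()] to every frame; after each frame the
#' track centre moves to that frame's measured centre of mass (unless the
#' chosen mask was empty, in which case it stays put).  Unreadable frames
#' are skipped with a warning.
#'
#' @param segmenter Segmenter function.
#' @param frames A `growth_frames` object, a list of `[H, W, C]` arrays, or
#'   a character vector of image paths.
#' @param state0 Initial [init_track()] state.
#' @param timestamps POSIXct timestamps (taken from `frames` when it is a
#'   `growth_frames`; parsed from filenames via [parse_frame_times()] when
#'   `frames` are paths and `timestamps` is `NULL`).
#' @return An object of class `growth_series`: `records` data frame,
#'   `masks` list, `scale_factors`.
#' @export
track_series <- function(segmenter, frames, state0, timestamps = NULL) {
  if (inherits(frames, "growth_frames")) {
    timestamps <- frames$times
    frames <- frames$frames
  }
  paths <- is.character(frames)
  if (paths && is.null(timestamps))
    timestamps <- parse_frame_times(frames)
  n <- length(frames)
  if (is.null(timestamps)) timestamps <- as.POSIXct(seq_len(n) * 3600,
                                                    origin = "2000-01-01",
                                                    tz = "UTC")
  state <- state0
  recs <- vector("list", n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    img <- if (paths) tryCatch(read_image(frames[i]), error = function(e) NULL)
      else frames[[i]]
    if (is.null(img)) {
      warning(sprintf("skipping unreadable frame %d (%s)", i,
                      if (paths) frames[i] else "in-memory"))
      next
    }
    m <- multiscale_measure(segmenter, img, state, frame_id = i,
                            timestamp = timestamps[i])
    recs[[i]] <- m$record
    masks[[i]] <- m$mask
    if (!m$record$empty) state$center <- m$center
  }
  keep <- !vapply(recs, is.null, TRUE)
  structure(list(records = do.call(rbind, recs[keep]),
                 masks = masks[keep],
                 scale_factors = scale_ladder()),
            class = "growth_series")
}

#' @export
print.growth_series <- function(x, ...) {
  cat(sprintf("<growth_series> %d records, %d flagged outliers\n",
              nrow(x$records), sum(x$records$outlier_flag)))
  invisible(x)
}

.subset_series <- function(series, keep) {
  series$records <- series$records[keep, , drop = FALSE]
  rownames(series$records) <- NULL
  series$masks <- series$masks[keep]
  series
}

#' Keep only daytime records
#'
#' Fixed cameras capture around the clock but evening/night measurements
#' are noticeably less stable; the growth curve is built from a whitelist
#' of times of day.  The default whitelist (5 capture times) turns an
#' 8-captures-a-day, 63-day series into 315 records.
#'
#' @param series A `growth_series`.
#' @param whitelist Character times of day (`"HH:MM"`).
#' @return The filtered `growth_series`.
#' @export
filter_daytime <- function(series,
                           whitelist = c("08:00", "09:49", "11:49",
                                         "13:49", "15:49")) {
  stopifnot(inherits(series, "growth_series"))
  keep <- format(series$records$timestamp, "%H:%M") %in% whitelist
  .subset_series(series, keep)
}

# Largest integer strictly below fraction * n (so e.g. 5% of 315 -> 15,
# 5% of 20 -> 0), guarded against floating-point noise.
.outlier_count <- function(n, fraction) {
  max(0L, as.integer(ceiling(fraction * n - 1e-9)) - 1L)
}

#' Flag high-CV records and replace their medians
#'
#' The K records with the largest coefficient of variation, where K is the
#' largest integer strictly below `fraction * N` (15 for the default 5% of
#' 315), are flagged as outliers; each flagged record's median area is
#' replaced by the median of the nearest earlier unflagged record
#' (chaining backwards over consecutive flags).  Undefined CVs count as
#' largest.  `manual_ids` adds manual overrides by frame id for confident
#' mistakes the CV rule missed.  A flagged first record with no earlier
#' unflagged record is left unreplaced with a warning.
#'
#' @param series A `growth_series`.
#' @param fraction Outlier fraction bound (default 0.05).
#' @param manual_ids Frame ids to flag unconditionally.
#' @return The `growth_series` with `outlier_flag`, `replaced_from` and
#'   replaced `median_area_px` values filled in.
#' @export
flag_and_replace_outliers <- function(series, fraction = 0.05,
                                      manual_ids = NULL) {
  stopifnot(inherits(series, "growth_series"))
  r <- series$records
  n <- nrow(r)
  if (n == 0) stop("empty series")
  K <- .outlier_count(n, fraction)
  cvs <- r$cv
  cvs[is.na(cvs)] <- Inf
  flag <- rep(FALSE, n)
  if (K > 0) flag[order(cvs, decreasing = TRUE)[seq_len(K)]] <- TRUE
  flag[r$frame_id %in% manual_ids] <- TRUE
  r$outlier_flag <- flag
  for (i in which(flag)) {
    j <- max(which(!flag[seq_len(i)]), -Inf)
    if (!is.finite(j)) {
      warning(sprintf("record %d flagged but has no earlier unflagged record",
                      r$frame_id[i]))
      next
    }
    r$median_area_px[i] <- r$median_area_px[j]
    r$replaced_from[i] <- r$frame_id[j]
  }
  series$records <- r
  series
}

#' Fit a polynomial growth curve
#'
#' Least-squares polynomial of the stated degree (default 5) of median
#' area against time (hours since the first record).
#'
#' @param series A `growth_series` with at least `degree + 1` records.
#' @param degree Polynomial degree.
#' @return `list(degree, coefficients, time_hours, fitted, reference_time)`
#'   of class `growth_fit`.
#' @export
fit_growth_curve <- function(series, degree = 5) {
  stopifnot(inherits(series, "growth_series"))
  r <- series$records
  if (nrow(r) < degree + 1)
    stop(sprintf("need at least %d records for a degree-%d fit",
                 degree + 1, degree))
  t_h <- as.numeric(r$timestamp - r$timestamp[1], units = "hours")
  fit <- stats::lm(r$median_area_px ~ poly(t_h, degree, raw = TRUE))
  structure(list(degree = degree,
                 coefficients = unname(stats::coef(fit)),
                 time_hours = t_h,
                 fitted = unname(stats::fitted(fit)),
                 reference_time = r$timestamp[1]),
            class = "growth_fit")
}

#' Fit the asymmetric sigmoid growth model
#'
#' Nonlinear least squares ([minpack.lm::nlsLM()]) fit of the
#' generalized-logistic curve of [growth_area()] to measured areas,
#' used to recover the asymptotic area from a tracked series.
#'
#' @param t_days Time in days.
#' @param areas Measured areas.
#' @param start Optional named start list (`a_inf`, `rate`, `t0`, `nu`).
#' @return Named coefficient vector (`a_inf`, `rate`, `t0`, `nu`).
#' @export
fit_growth_sigmoid <- function(t_days, areas, start = NULL) {
  if (is.null(start))
    start <- list(a_inf = max(areas) * 1.05, rate = 0.1,
                  t0 = stats::median(t_days), nu = 1)
  fit <- minpack.lm::nlsLM(
    areas ~ a_inf * (1 + exp(-rate * (t_days - t0)))^(-1 / nu),
    start = start,
    lower = c(a_inf = 0, rate = 1e-4, t0 = min(t_days) - 100, nu = 0.05),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  stats::coef(fit)
}
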