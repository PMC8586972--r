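# Shared fixtures, all generated in code.

tiny_net <- function(side = 16, base = 2, depth = 2, seed = 1) {
  build_network(network_config(input_side = side, base_channels = base,
                               depth = depth), seed = seed)
}

rand_image <- function(side = 16, channels = 3, seed = 1) {
  set.seed(seed)
  array(runif(side * side * channels), c(side, side, channels))
}

rand_mask <- function(side = 16, p = 0.4, seed = 1) {
  set.seed(seed)
  matrix(rbinom(side * side, 1, p), side, side)
}

# A minimal growth_series built directly from per-record values, for tests
# of the filtering/outlier/fitting stages that do not need real tracking.
fake_series <- function(medians, cvs = rep(0.01, length(medians)),
                        timestamps = NULL) {
  n <- length(medians)
  if (is.null(timestamps))
    timestamps <- as.POSIXct("2020-08-13 08:00:00", tz = "UTC") +
      3600 * seq_len(n)
  r <- data.frame(frame_id = seq_len(n), timestamp = timestamps)
  for (cl in cropseg:::.area_cols()) r[[cl]] <- medians
  r$median_area_px <- medians
  r$cv <- cvs
  r$center_x <- 0; r$center_y <- 0
  r$chosen_scale <- 1
  r$empty <- FALSE
  r$outlier_flag <- FALSE
  r$replaced_from <- NA_integer_
  structure(list(records = r,
                 masks = replicate(n, matrix(1, 2, 2), simplify = FALSE),
                 scale_factors = scale_ladder()),
            class = "growth_series")
}

# Segmenter stub returning a fixed mask regardless of the crop.
const_segmenter <- function(mask) {
  fn <- function(image, request) mask
  attr(fn, "input_side") <- nrow(mask)
  fn
}
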