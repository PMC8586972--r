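# Synthetic scenes: a central star-convex ("roundish") object on a textured
# background with off-centre distractors, plus growth series whose object
# area follows a generalized-logistic (asymmetric sigmoid) curve.

#' Specification of a synthetic central-object scene
#'
#' The object boundary is a star-convex curve
#' `R(theta) = r0 * (1 + sum_k a_k cos(k*theta + phi_k))` around a jittered
#' centre; its analytic area is `pi * r0^2 * (1 + sum(a_k^2)/2)`.
#' Distractors share the object's colour family but never cover the canvas
#' centre, so "the central object" stays well defined.
#'
#' @param canvas_side Canvas side in pixels.
#' @param radius Object base radius `r0`; a length-2 vector samples
#'   uniformly from the range.
#' @param n_harmonics,harmonic_amp Number and maximum amplitude of the
#'   boundary harmonics; `n_harmonics * harmonic_amp` must stay below 1 so
#'   the radius remains positive.
#' @param center_jitter Centre jitter as a fraction of the canvas side.
#' @param n_distractors Number of off-centre distractor objects.
#' @param distractor_scale Distractor radius range relative to the object's.
#' @param distractor_match If `TRUE`, distractors carry exactly the
#'   object's colour (other fruit of the same kind), so only spatial
#'   context -- centrality -- separates them from the target; the default
#'   `FALSE` jitters their colour slightly.
#' @param illum_amp Amplitude of the linear illumination gradient.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param seed Optional default seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(canvas_side = 64, radius = c(10, 22), n_harmonics = 3,
                       harmonic_amp = 0.08, center_jitter = 0.08,
                       n_distractors = 2, distractor_scale = c(0.3, 0.55),
                       distractor_match = FALSE,
                       illum_amp = 0.15, noise_sd = 0.02, seed = NULL) {
  stopifnot(canvas_side > 0, all(radius > 0), n_harmonics >= 0)
  if (n_harmonics * harmonic_amp >= 1)
    stop("sum of harmonic amplitudes must stay below 1 (star-convex object)")
  structure(list(canvas_side = as.integer(canvas_side), radius = radius,
                 n_harmonics = n_harmonics, harmonic_amp = harmonic_amp,
                 center_jitter = center_jitter, n_distractors = n_distractors,
                 distractor_scale = distractor_scale,
                 distractor_match = isTRUE(distractor_match),
                 illum_amp = illum_amp,
                 noise_sd = noise_sd, seed = seed),
            class = "scene_spec")
}

# Mask of a star-convex object on an n x n canvas.  Coordinates are 0-based
# from the top-left corner; the centre of pixel (i, j) (1-based indices) is
# (x, y) = (j - 0.5, i - 0.5).
.star_mask <- function(n, cx, cy, r0, a, phi) {
  x <- matrix(rep(seq_len(n) - 0.5, each = n), n, n)
  y <- matrix(rep(seq_len(n) - 0.5, n), n, n)
  dx <- x - cx; dy <- y - cy
  rr <- sqrt(dx^2 + dy^2)
  R <- r0
  if (length(a)) {
    th <- atan2(dy, dx)
    mod <- 1
    for (k in seq_along(a)) mod <- mod + a[k] * cos(k * th + phi[k])
    R <- r0 * mod
  }
  (rr <= R) * 1
}

.star_area <- function(r0, a) pi * r0^2 * (1 + sum(a^2) / 2)

.star_polygon <- function(cx, cy, r0, a, phi, n_vertices = 72) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  mod <- 1
  for (k in seq_along(a)) mod <- mod + a[k] * cos(k * th + phi[k])
  cbind(x = cx + r0 * mod * cos(th), y = cy + r0 * mod * sin(th))
}

# Low-frequency additive texture field on an n x n canvas.
.texture_field <- function(n, amp = 0.04, n_waves = 2) {
  out <- matrix(0, n, n)
  x <- matrix(rep(seq_len(n), each = n), n, n) / n
  y <- matrix(rep(seq_len(n), n), n, n) / n
  for (i in seq_len(n_waves)) {
    f <- stats::runif(2, 1, 4)
    ph <- stats::runif(1, 0, 2 * pi)
    out <- out + amp * sin(2 * pi * (f[1] * x + f[2] * y) + ph)
  }
  out
}

# Sample the appearance (colours, texture phases, illumination direction)
# of a scene; kept separate so a growth series can freeze it across frames.
.sample_appearance <- function(spec) {
  list(ob_col = c(stats::runif(1, 0.65, 0.85), stats::runif(1, 0.45, 0.60),
                  stats::runif(1, 0.20, 0.35)),
       bg_col = c(stats::runif(1, 0.20, 0.35), stats::runif(1, 0.40, 0.55),
                  stats::runif(1, 0.18, 0.30)),
       illum_dir = stats::runif(1, 0, 2 * pi))
}

# Sample a distractor layout.  Distractors sit off-centre: the disk of each
# never covers the canvas centre (exclusion margin of 8% of the side).
.sample_distractors <- function(spec, r_obj, appearance) {
  n <- spec$canvas_side
  out <- list()
  if (spec$n_distractors < 1) return(out)
  for (i in seq_len(spec$n_distractors)) {
    rd <- r_obj * stats::runif(1, spec$distractor_scale[1], spec$distractor_scale[2])
    for (try in 1:30) {
      ang <- stats::runif(1, 0, 2 * pi)
      dist <- stats::runif(1, 0.30, 0.52) * n
      cx <- n / 2 + dist * cos(ang)
      cy <- n / 2 + dist * sin(ang)
      if (sqrt((cx - n / 2)^2 + (cy - n / 2)^2) > rd + 0.08 * n) break
    }
    col <- if (isTRUE(spec$distractor_match)) appearance$ob_col else
      pmin(pmax(appearance$ob_col + stats::rnorm(3, sd = 0.06), 0), 1)
    out[[i]] <- list(cx = cx, cy = cy, r = rd,
                     a = stats::runif(2, 0, 0.06),
                     phi = stats::runif(2, 0, 2 * pi), col = col)
  }
  out
}

# Render one scene.  geom = list(cx, cy, r0, a, phi).
.render_scene <- function(spec, geom, distractors, appearance,
                          night = FALSE, night_dim = 0.35) {
  n <- spec$canvas_side
  mask <- .star_mask(n, geom$cx, geom$cy, geom$r0, geom$a, geom$phi)
  x <- matrix(rep(seq_len(n) - 0.5, each = n), n, n) / n - 0.5
  y <- matrix(rep(seq_len(n) - 0.5, n), n, n) / n - 0.5
  illum <- 1 + spec$illum_amp * 2 *
    (x * cos(appearance$illum_dir) + y * sin(appearance$illum_dir))
  bg_tex <- .texture_field(n)
  ob_tex <- .texture_field(n, amp = 0.03)
  img <- array(0, dim = c(n, n, 3))
  dmask <- vector("list", length(distractors))
  for (i in seq_along(distractors)) {
    d <- distractors[[i]]
    dmask[[i]] <- .star_mask(n, d$cx, d$cy, d$r, d$a, d$phi)
  }
  for (ch in 1:3) {
    layer <- appearance$bg_col[ch] * (1 + bg_tex)
    for (i in seq_along(distractors)) {
      d <- distractors[[i]]
      layer[dmask[[i]] == 1] <- d$col[ch] * (1 + ob_tex[dmask[[i]] == 1])
    }
    layer[mask == 1] <- appearance$ob_col[ch] * (1 + ob_tex[mask == 1])
    img[, , ch] <- layer * illum
  }
  if (night) img <- img * night_dim
  sdn <- spec$noise_sd * if (night) 2 else 1
  if (sdn > 0) img <- img + stats::rnorm(length(img), sd = sdn)
  img[img < 0] <- 0
  img[img > 1] <- 1
  list(image = img, mask = mask)
}

#' Generate an annotated synthetic scene
#'
#' @param spec A [scene_spec()].
#' @param seed Integer seed; the same seed gives a byte-identical scene.
#' @return A list with `image` (`[H, W, 3]`, values in `[0, 1]`), `mask`
#'   (0/1), `center` (x, y in fractional pixels from the top-left), the
#'   base `radius`, the boundary `harmonics`, `area_analytic`, `area_px`
#'   (mask pixel count) and a `polygon` approximation of the boundary.
#' @export
generate_scene <- function(spec = scene_spec(), seed = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  if (is.null(seed)) seed <- spec$seed
  if (!is.null(seed)) set.seed(seed)
  n <- spec$canvas_side
  r0 <- if (length(spec$radius) == 2)
    stats::runif(1, spec$radius[1], spec$radius[2]) else spec$radius
  a <- if (spec$n_harmonics > 0)
    stats::runif(spec$n_harmonics, 0, spec$harmonic_amp) else numeric(0)
  phi <- stats::runif(length(a), 0, 2 * pi)
  cx <- n / 2 + stats::runif(1, -1, 1) * spec$center_jitter * n
  cy <- n / 2 + stats::runif(1, -1, 1) * spec$center_jitter * n
  appearance <- .sample_appearance(spec)
  distractors <- .sample_distractors(spec, r0, appearance)
  sc <- .render_scene(spec, list(cx = cx, cy = cy, r0 = r0, a = a, phi = phi),
                      distractors, appearance)
  list(image = sc$image, mask = sc$mask, center = c(x = cx, y = cy),
       radius = r0, harmonics = list(a = a, phi = phi),
       area_analytic = .star_area(r0, a), area_px = sum(sc$mask),
       polygon = .star_polygon(cx, cy, r0, a, phi))
}

#' Generalized-logistic (asymmetric sigmoid) area curve
#'
#' `A(t) = A_inf * (1 + exp(-g * (t - t0)))^(-1/nu)`: monotone increasing,
#' with asymmetry about the inflection controlled by `nu` (`nu = 1` is the
#' symmetric logistic, at which `A(t0) = A_inf / 2`).
#'
#' @param t Time in days.
#' @param a_inf Asymptotic area (pixels^2).
#' @param rate Growth rate per day.
#' @param t0 Inflection-related time shift (days).
#' @param nu Asymmetry parameter (> 0).
#' @return Areas at `t`.
#' @export
growth_area <- function(t, a_inf, rate, t0, nu) {
  a_inf * (1 + exp(-rate * (t - t0)))^(-1 / nu)
}

#' Specification of a synthetic growth series
#'
#' Emulates a fixed camera photographing a growing fruit: several captures
#' per day over many days, the object's true mask area following the
#' asymmetric sigmoid of [growth_area()], the centre drifting slowly, and
#' evening/night captures darkened and noisier.
#'
#' @param canvas_side Frame side in pixels.
#' @param a_inf,rate,t0,nu Growth-curve parameters, see [growth_area()].
#' @param days Number of days.
#' @param times Character capture times of day (`"HH:MM"`); the default is
#'   eight captures a day at 8:00, 9:49, 11:49, 13:49, 15:49, 17:49, 19:49,
#'   21:49.
#' @param night_times Subset of `times` rendered darkened/noisier.
#' @param night_dim Brightness factor for night frames.
#' @param drift_sd Per-frame centre drift standard deviation (pixels).
#' @param start_date First capture date (`"YYYY-MM-DD"`).
#' @param n_harmonics,harmonic_amp,n_distractors,illum_amp,noise_sd As in
#'   [scene_spec()]; the object shape and scene appearance are frozen over
#'   the series (it is the same fruit and the same camera).
#' @param seed Seed for all randomness of the series.
#' @return An object of class `growth_spec`.
#' @export
growth_spec <- function(canvas_side = 192, a_inf = 3500, rate = 0.1,
                        t0 = 10, nu = 1.5, days = 63,
                        times = c("08:00", "09:49", "11:49", "13:49",
                                  "15:49", "17:49", "19:49", "21:49"),
                        night_times = c("17:49", "19:49", "21:49"),
                        night_dim = 0.35, drift_sd = 1.0,
                        start_date = "2020-08-13", n_harmonics = 3,
                        harmonic_amp = 0.05, n_distractors = 2,
                        illum_amp = 0.12, noise_sd = 0.02, seed = 1) {
  stopifnot(a_inf > 0, rate > 0, nu > 0, days >= 1, length(times) >= 1)
  structure(list(canvas_side = as.integer(canvas_side), a_inf = a_inf,
                 rate = rate, t0 = t0, nu = nu, days = as.integer(days),
                 times = times, night_times = night_times,
                 night_dim = night_dim, drift_sd = drift_sd,
                 start_date = start_date, n_harmonics = n_harmonics,
                 harmonic_amp = harmonic_amp, n_distractors = n_distractors,
                 illum_amp = illum_amp, noise_sd = noise_sd, seed = seed),
            class = "growth_spec")
}

#' Generate a synthetic growth series with ground truth
#'
#' @param spec A [growth_spec()].
#' @param out_dir Optional directory; when given, frames are written as PNG
#'   files (named with their timestamps) together with a `truth.csv`.
#' @return A list of class `growth_frames` with `frames` (list of
#'   `[H, W, 3]` arrays), `times` (POSIXct) and a `truth` data frame
#'   (`frame`, `time`, `t_days`, `area_true`, `area_px`, `cx`, `cy`, `r`,
#'   `night`), plus the frozen scene parameters used by the oracle
#'   segmenter.
#' @export
generate_growth_series <- function(spec = growth_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "growth_spec"))
  set.seed(spec$seed)
  n <- spec$canvas_side
  a <- if (spec$n_harmonics > 0)
    stats::runif(spec$n_harmonics, 0, spec$harmonic_amp) else numeric(0)
  phi <- stats::runif(length(a), 0, 2 * pi)
  appearance <- .sample_appearance(spec)
  shape_factor <- 1 + sum(a^2) / 2
  r_inf <- sqrt(spec$a_inf / (pi * shape_factor))
  sspec <- scene_spec(canvas_side = n, radius = r_inf,
                      n_harmonics = spec$n_harmonics,
                      harmonic_amp = spec$harmonic_amp,
                      n_distractors = spec$n_distractors,
                      illum_amp = spec$illum_amp, noise_sd = spec$noise_sd)
  distractors <- .sample_distractors(sspec, 0.6 * r_inf, appearance)

  tod <- as.difftime(paste0(spec$times, ":00"), units = "hours",
                     format = "%H:%M:%S")
  day0 <- as.Date(spec$start_date)
  times <- as.POSIXct(rep(day0 + seq_len(spec$days) - 1, each = length(tod)),
                      tz = "UTC") + rep(as.numeric(tod, units = "secs"),
                                        spec$days)
  t_days <- as.numeric(times - times[1], units = "days")
  nframes <- length(times)

  # centre drift: random walk clamped near the canvas centre
  drift <- matrix(stats::rnorm(2 * nframes, sd = spec$drift_sd), ncol = 2)
  path <- apply(drift, 2, cumsum)
  if (is.null(dim(path))) path <- matrix(path, ncol = 2)
  lim <- 0.12 * n
  path <- pmin(pmax(path, -lim), lim)
  cx <- n / 2 + path[, 1]
  cy <- n / 2 + path[, 2]

  night <- format(times, "%H:%M") %in% spec$night_times
  frames <- vector("list", nframes)
  area_true <- growth_area(t_days, spec$a_inf, spec$rate, spec$t0, spec$nu)
  r_t <- sqrt(area_true / (pi * shape_factor))
  area_px <- numeric(nframes)
  for (i in seq_len(nframes)) {
    sc <- .render_scene(sspec,
                        list(cx = cx[i], cy = cy[i], r0 = r_t[i], a = a,
                             phi = phi),
                        distractors, appearance, night = night[i],
                        night_dim = spec$night_dim)
    frames[[i]] <- sc$image
    area_px[i] <- sum(sc$mask)
  }
  truth <- data.frame(frame = seq_len(nframes), time = times,
                      t_days = t_days, area_true = area_true,
                      area_px = area_px, cx = cx, cy = cy, r = r_t,
                      night = night)
  out <- structure(list(frames = frames, times = times, truth = truth,
                        params = list(a = a, phi = phi,
                                      appearance = appearance,
                                      distractors = distractors,
                                      shape_factor = shape_factor),
                        spec = spec),
                   class = "growth_frames")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(nframes)) {
      fn <- sprintf("frame_%04d_%s.png", i, format(times[i], "%Y%m%d_%H%M"))
      png::writePNG(frames[[i]], file.path(out_dir, fn))
    }
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  }
  out
}

#' Rasterize a polygon into a binary mask
#'
#' Even-odd fill: a pixel is foreground iff its centre lies inside the
#' polygon.  Pixel centres follow the package convention (0-based index +
#' 0.5, x = column, y = row, origin at the top-left).
#'
#' @param vertices An `n x 2` matrix of (x, y) vertices, `n >= 3`.
#' @param dims Canvas dims `c(H, W)`.
#' @return An `[H, W]` 0/1 mask.
#' @export
rasterize_polygon <- function(vertices, dims) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3) stop("a polygon needs at least 3 vertices")
  H <- dims[1]; W <- dims[2]
  bnd <- rbind(vertices, vertices[1, ])
  px <- rep(seq_len(W) - 0.5, each = H)
  py <- rep(seq_len(H) - 0.5, W)
  inside <- mgcv::in.out(bnd, cbind(px, py))
  matrix(as.numeric(inside), H, W)
}

#' Ground-truth (oracle) segmenter for synthetic growth series
#'
#' Returns a segmenter with the same calling contract as the trained
#' network segmenter ([make_network_segmenter()]): it receives a square
#' crop plus the window geometry and returns the exact ground-truth mask of
#' the generator's object resampled to `input_side` (the star-shape
#' inequality is evaluated directly at the resampled pixel centres, so
#' there is no interpolation error).  A window entirely outside the object
#' yields an empty mask.
#'
#' `corrupt_frames` marks frame ids whose masks are perturbed by a random
#' per-call radius factor; such frames disagree across measurement scales
#' and acquire a large coefficient of variation, exercising the outlier
#' rule downstream.
#'
#' @param series A [generate_growth_series()] result.
#' @param input_side Output mask side in pixels.
#' @param corrupt_frames Integer frame ids to corrupt.
#' @return A `function(image, request)` with attribute `input_side`.
#' @export
make_oracle_segmenter <- function(series, input_side = 64,
                                  corrupt_frames = integer(0)) {
  stopifnot(inherits(series, "growth_frames"))
  truth <- series$truth
  a <- series$params$a; phi <- series$params$phi
  fn <- function(image, request) {
    k <- request$frame
    P <- request$out
    r0 <- truth$r[k]
    if (k %in% corrupt_frames) r0 <- r0 * stats::runif(1, 0.4, 1.7)
    sc <- request$side / P
    fx <- request$x0 + (seq_len(P) - 0.5) * sc
    fy <- request$y0 + (seq_len(P) - 0.5) * sc
    dx <- matrix(rep(fx - truth$cx[k], each = P), P, P)
    dy <- matrix(rep(fy - truth$cy[k], P), P, P)
    rr <- sqrt(dx^2 + dy^2)
    R <- r0
    if (length(a)) {
      th <- atan2(dy, dx)
      mod <- 1
      for (j in seq_along(a)) mod <- mod + a[j] * cos(j * th + phi[j])
      R <- r0 * mod
    }
    (rr <= R) * 1
  }
  attr(fn, "input_side") <- as.integer(input_side)
  fn
}
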