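# Raster helpers -------------------------------------------------------

.rev_dim1 <- function(a) {
  idx <- rep(list(quote(expr = )), length(dim(a)))
  idx[[1]] <- rev(seq_len(dim(a)[1]))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

.rev_dim2 <- function(a) {
  idx <- rep(list(quote(expr = )), length(dim(a)))
  idx[[2]] <- rev(seq_len(dim(a)[2]))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# 90-degree counter-clockwise rotation about the first two dims.
.rot90 <- function(a) {
  nd <- length(dim(a))
  ap <- aperm(a, c(2, 1, seq_len(nd)[-(1:2)]))
  .rev_dim1(ap)
}

.as_raster <- function(x) {
  if (is.null(dim(x))) stop("raster input required")
  if (length(dim(x)) == 2) {
    d <- dim(x); dim(x) <- c(d, 1L); attr(x, "was2d") <- TRUE
  }
  x
}

#' Resize a raster
#'
#' Thin wrapper over [EBImage::resize()] operating on `[H, W]` or
#' `[H, W, C]` arrays.  `"bilinear"` for images, `"nearest"` for binary
#' masks (values are never interpolated).
#'
#' @param a Array `[H, W]` or `[H, W, C]`.
#' @param h,w Output sides in pixels.
#' @param method `"bilinear"` or `"nearest"`.
#' @return The resized array with the same number of dimensions as `a`.
#' @export
resize_raster <- function(a, h, w = h, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  d2 <- length(dim(a)) == 2
  out <- EBImage::resize(a, w = h, h = w,
                         filter = if (method == "bilinear") "bilinear" else "none")
  out <- as.array(out)
  if (d2 && length(dim(out)) > 2) dim(out) <- dim(out)[1:2]
  out
}

# Dihedral group of the square ----------------------------------------

#' The 8 square-preserving transforms (dihedral group D4)
#'
#' Each element is `list(rot, flip)`: an optional horizontal mirror applied
#' first, followed by `rot` quarter-turn counter-clockwise rotations.
#' Elements 1--4 are the pure rotations (rot = 0..3), elements 5--8 the
#' mirrored ones in the same rotation order.
#'
#' @return A list of 8 `list(rot, flip)` elements.
#' @export
d4_transforms <- function() {
  out <- vector("list", 8)
  for (k in 1:8) out[[k]] <- list(rot = (k - 1) %% 4, flip = k > 4)
  out
}

#' Apply / invert a dihedral transform
#'
#' @param a Square raster (`[H, W]`, `[H, W, C]` or `[H, W, C, N]`).
#' @param transform A `list(rot, flip)` as returned by [d4_transforms()].
#' @return The transformed raster (`d4_apply`), or the inverse transform as
#'   a `list(rot, flip)` (`d4_inverse`).
#' @export
d4_apply <- function(a, transform) {
  if (transform$flip) a <- .rev_dim2(a)
  r <- transform$rot %% 4
  while (r > 0) {
    a <- .rot90(a)
    r <- r - 1
  }
  a
}

#' @rdname d4_apply
#' @export
d4_inverse <- function(transform) {
  if (transform$flip) transform  # mirrored elements are involutions
  else list(rot = (4 - transform$rot) %% 4, flip = FALSE)
}

#' Orbit of a square raster under the dihedral group
#'
#' Returns the 8 images obtained by `{identity, 3 rotations} x {no flip,
#' horizontal flip}` in the deterministic order of [d4_transforms()].
#'
#' @param image Square raster.
#' @return A list of 8 elements `list(image, rot, flip)`.
#' @export
d4_orbit <- function(image) {
  d <- dim(image)
  if (is.null(d) || d[1] != d[2]) stop("d4_orbit requires a square raster")
  lapply(d4_transforms(), function(tf)
    list(image = d4_apply(image, tf), rot = tf$rot, flip = tf$flip))
}

#' Segment an image with 8-fold test-time augmentation
#'
#' The image is pushed through the network under each of the 8 dihedral
#' transforms; each output is realigned by the inverse transform; the 8
#' aligned probability maps are averaged and thresholded.  Averaging over
#' the full orbit makes the result equivariant under the group.
#'
#' @param network A `crop_network`.
#' @param image Square `[H, W, C]` image, side divisible by `2^depth`.
#' @param threshold Binarization threshold (default 0.5).
#' @return `list(prob, mask)`: the averaged `[H, W]` probability map and
#'   its 0/1 mask.
#' @export
tta_segment <- function(network, image, threshold = 0.5) {
  d <- dim(image)
  if (d[1] != d[2]) stop("tta_segment requires a square image")
  acc <- matrix(0, d[1], d[2])
  for (tf in d4_transforms()) {
    xi <- d4_apply(image, tf)
    p <- forward(network, xi)[, , 1, 1]
    acc <- acc + d4_apply(p, d4_inverse(tf))
  }
  avg <- acc / 8
  list(prob = avg, mask = binarize(avg, threshold))
}

# Training-time augmentation -------------------------------------------

#' Specification of random training augmentations
#'
#' Geometric changes (size alterations, horizontal and vertical flips,
#' quarter-turn rotations) are applied identically to image and mask (the
#' mask via nearest-neighbour resampling so it stays binary); photometric
#' jitter (brightness / contrast / saturation) is applied to the image only
#' and clamped to `[0, 1]`.
#'
#' @param scale_range Range of the isotropic size-alteration factor; a
#'   factor f rescales the content so mask areas scale with f^2.
#' @param hflip_p,vflip_p Flip probabilities.
#' @param rot90 Include random quarter-turn rotations?
#' @param brightness,contrast,saturation Jitter amplitudes (0 disables).
#' @param seed Optional default seed.
#' @return An object of class `augment_spec`.
#' @export
augment_spec <- function(scale_range = c(0.9, 1.1), hflip_p = 0.5,
                         vflip_p = 0.5, rot90 = TRUE, brightness = 0.08,
                         contrast = 0.08, saturation = 0.08, seed = NULL) {
  stopifnot(length(scale_range) == 2, all(scale_range > 0),
            scale_range[1] <= scale_range[2],
            brightness >= 0, contrast >= 0, saturation >= 0)
  structure(list(scale_range = scale_range, hflip_p = hflip_p,
                 vflip_p = vflip_p, rot90 = rot90, brightness = brightness,
                 contrast = contrast, saturation = saturation, seed = seed),
            class = "augment_spec")
}

.center_fit <- function(a, H, W, fill = c("edge", "zero")) {
  fill <- match.arg(fill)
  d <- dim(a)
  off_r <- floor((d[1] - H) / 2)
  off_c <- floor((d[2] - W) / 2)
  ir <- seq_len(H) + off_r
  ic <- seq_len(W) + off_c
  if (fill == "edge") {
    ir <- pmin(pmax(ir, 1), d[1])
    ic <- pmin(pmax(ic, 1), d[2])
    if (length(d) == 2) a[ir, ic, drop = FALSE] else a[ir, ic, , drop = FALSE]
  } else {
    out <- array(0, dim = c(H, W, if (length(d) > 2) d[3]))
    keep_r <- ir >= 1 & ir <= d[1]
    keep_c <- ic >= 1 & ic <= d[2]
    if (length(d) == 2) {
      out[keep_r, keep_c] <- a[ir[keep_r], ic[keep_c], drop = FALSE]
      dim(out) <- c(H, W)
    } else {
      out[keep_r, keep_c, ] <- a[ir[keep_r], ic[keep_c], , drop = FALSE]
    }
    out
  }
}

#' Randomly augment an annotated sample
#'
#' @param sample `list(image, mask)` with matching spatial dims.
#' @param spec An [augment_spec()].
#' @param seed Optional seed; the same seed gives identical output.
#' @return The augmented `list(image, mask)`.
#' @export
random_augment <- function(sample, spec = augment_spec(), seed = NULL) {
  stopifnot(inherits(spec, "augment_spec"))
  if (is.null(seed)) seed <- spec$seed
  if (!is.null(seed)) set.seed(seed)
  img <- sample$image
  msk <- sample$mask
  if (!identical(dim(img)[1:2], dim(msk)[1:2]))
    stop("image and mask dims differ")
  if (stats::runif(1) < spec$hflip_p) {
    img <- .rev_dim2(img); msk <- .rev_dim2(msk)
  }
  if (stats::runif(1) < spec$vflip_p) {
    img <- .rev_dim1(img); msk <- .rev_dim1(msk)
  }
  if (isTRUE(spec$rot90) && dim(img)[1] == dim(img)[2]) {
    k <- sample(0:3, 1)
    for (i in seq_len(k)) {
      img <- .rot90(img); msk <- .rot90(msk)
    }
  }
  f <- stats::runif(1, spec$scale_range[1], spec$scale_range[2])
  if (abs(f - 1) > 1e-8) {
    H <- dim(img)[1]; W <- dim(img)[2]
    nh <- max(2, round(H * f)); nw <- max(2, round(W * f))
    img <- resize_raster(img, nh, nw, "bilinear")
    msk <- resize_raster(msk, nh, nw, "nearest")
    img <- .center_fit(img, H, W, "edge")
    msk <- .center_fit(msk, H, W, "zero")
  }
  if (spec$brightness > 0)
    img <- img + stats::runif(1, -spec$brightness, spec$brightness)
  if (spec$contrast > 0) {
    cm <- stats::runif(1, 1 - spec$contrast, 1 + spec$contrast)
    mu <- mean(img)
    img <- (img - mu) * cm + mu
  }
  if (spec$saturation > 0 && length(dim(img)) == 3 && dim(img)[3] == 3) {
    sf <- stats::runif(1, 1 - spec$saturation, 1 + spec$saturation)
    gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    for (ch in 1:3) img[, , ch] <- gray + (img[, , ch] - gray) * sf
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  msk <- (msk >= 0.5) * 1
  list(image = img, mask = msk)
}
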