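#' Configuration for a central-object segmentation network
#'
#' Describes a fully convolutional encoder--decoder network for segmenting
#' the central roundish object in an image.  The reference geometry is
#' `depth = 7` with `base_channels = 16` on 512-pixel inputs (the deep
#' variant); `depth = 4` gives the shallow, U-Net-like analogue.
#'
#' The encoder downsamples `depth` times with 2x2 stride-2 convolutions that
#' double the channel count, so the bottleneck feature map has side
#' `input_side / 2^depth` and `base_channels * 2^depth` channels.  The
#' decoder mirrors it with 2x2 stride-2 transposed convolutions that halve
#' the channels, concatenating the same-resolution encoder output at every
#' stage (skip connections).
#'
#' @param input_side Nominal input side in pixels.  The network is fully
#'   convolutional; any side divisible by `2^depth` is accepted at run time.
#' @param in_channels Number of input channels (3 for RGB).
#' @param base_channels Channel count after the stem; doubles per stage.
#' @param depth Number of downsampling stages (7 = deep, 4 = shallow).
#' @param out_channels Number of output channels (1 = probability map).
#' @return An object of class `crop_config`.
#' @examples
#' cfg <- network_config(input_side = 64, base_channels = 8, depth = 4)
#' network_summary(cfg)
#' @export
network_config <- function(input_side = 512, in_channels = 3,
                           base_channels = 16, depth = 7, out_channels = 1) {
  if (length(depth) != 1 || depth < 0 || depth != round(depth))
    stop("depth must be a non-negative integer")
  if (base_channels < 1) stop("base_channels must be >= 1")
  if (in_channels < 1) stop("in_channels must be >= 1")
  if (out_channels < 1) stop("out_channels must be >= 1")
  if (input_side < 1) stop("input_side must be positive")
  if (input_side %% 2^depth != 0)
    stop(sprintf("input_side (%d) must be divisible by 2^depth (%d)",
                 input_side, 2^depth))
  if (input_side / 2^depth < 1)
    stop("bottleneck side input_side / 2^depth must be >= 1")
  structure(list(input_side = as.integer(input_side),
                 in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 out_channels = as.integer(out_channels)),
            class = "crop_config")
}

#' Stage-by-stage geometry of a network configuration
#'
#' Pure shape introspection: feature-map side and channel count at the stem,
#' at every encoder stage, and at the bottleneck, without materializing any
#' weights.
#'
#' @param config A [network_config()].
#' @return A list with a `stages` data frame (`stage`, `side`, `channels`)
#'   and the scalar `bottleneck_side`.
#' @export
network_summary <- function(config) {
  stopifnot(inherits(config, "crop_config"))
  d <- seq_len(config$depth)
  stages <- data.frame(
    stage = c("stem", if (config$depth > 0) paste0("encoder", d)),
    side = c(config$input_side,
             if (config$depth > 0) config$input_side / 2^d),
    channels = c(config$base_channels,
                 if (config$depth > 0) config$base_channels * 2^d))
  list(stages = stages, bottleneck_side = config$input_side / 2^config$depth)
}

.bn_channels <- function(config) {
  b <- config$base_channels
  ch <- c(stem1 = b, stem2 = b)
  for (d in seq_len(config$depth)) {
    cd <- b * 2^d
    ch[paste0("enc", d, ".down")] <- cd
    ch[paste0("enc", d, ".a")] <- cd
    ch[paste0("enc", d, ".b")] <- cd
    cu <- b * 2^(d - 1)
    ch[paste0("dec", d, ".up")] <- cu
    if (d > 1) {
      ch[paste0("dec", d, ".a")] <- cu
      ch[paste0("dec", d, ".b")] <- cu
    }
  }
  ch["head1"] <- b
  ch["head2"] <- b
  ch
}

#' Build a segmentation network
#'
#' Instantiates the encoder--decoder network described by `config`:
#' a stem of two 3x3 convolutions (`in_channels` -> base -> base); `depth`
#' encoder stages (2x2 stride-2 convolution doubling the channels, then two
#' 3x3 convolutions); a mirrored decoder (2x2 stride-2 transposed
#' convolution halving the channels, concatenation with the encoder skip,
#' then 3x3 convolutions); and a head of three 3x3 convolutions reducing the
#' final full-resolution concatenation (2*base -> base -> base ->
#' `out_channels`) followed by a sigmoid, so for the default base of 16 the
#' channel schedule reads 3->16->16 on the way in and 32->16->16->1 on the
#' way out.  Batch normalization and ReLU follow every convolution except
#' the output convolution.
#'
#' Weights are He-initialized at random; pass `seed` for reproducibility.
#'
#' @param config A [network_config()].
#' @param seed Optional integer seed for weight initialization.
#' @return An object of class `crop_network`.
#' @export
build_network <- function(config, seed = NULL) {
  stopifnot(inherits(config, "crop_config"))
  if (!is.null(seed)) set.seed(seed)
  b <- config$base_channels
  p <- list()
  add_conv <- function(name, dims) {
    p[[paste0(name, ".w")]] <<- init_conv(dims)
    p[[paste0(name, ".b")]] <<- numeric(dims[length(dims)])
  }
  add_bn <- function(name, ch) {
    p[[paste0(name, ".gamma")]] <<- rep(1, ch)
    p[[paste0(name, ".beta")]] <<- numeric(ch)
  }
  add_conv("stem1", c(3, 3, config$in_channels, b)); add_bn("stem1", b)
  add_conv("stem2", c(3, 3, b, b)); add_bn("stem2", b)
  for (d in seq_len(config$depth)) {
    cin <- b * 2^(d - 1); cd <- 2 * cin
    add_conv(paste0("enc", d, ".down"), c(2, 2, cin, cd))
    add_bn(paste0("enc", d, ".down"), cd)
    add_conv(paste0("enc", d, ".a"), c(3, 3, cd, cd)); add_bn(paste0("enc", d, ".a"), cd)
    add_conv(paste0("enc", d, ".b"), c(3, 3, cd, cd)); add_bn(paste0("enc", d, ".b"), cd)
    # decoder stage d: transposed conv from cd down to cin channels
    p[[paste0("dec", d, ".up.w")]] <- init_conv(c(cd, 2, 2, cin))
    p[[paste0("dec", d, ".up.b")]] <- numeric(cin)
    add_bn(paste0("dec", d, ".up"), cin)
    if (d > 1) {
      add_conv(paste0("dec", d, ".a"), c(3, 3, cd, cin)); add_bn(paste0("dec", d, ".a"), cin)
      add_conv(paste0("dec", d, ".b"), c(3, 3, cin, cin)); add_bn(paste0("dec", d, ".b"), cin)
    }
  }
  head_in <- if (config$depth > 0) 2 * b else b
  add_conv("head1", c(3, 3, head_in, b)); add_bn("head1", b)
  add_conv("head2", c(3, 3, b, b)); add_bn("head2", b)
  add_conv("head3", c(3, 3, b, config$out_channels))
  buffers <- new.env(parent = emptyenv())
  for (nm in names(.bn_channels(config))) {
    ch <- .bn_channels(config)[[nm]]
    buffers[[paste0(nm, ".mean")]] <- numeric(ch)
    buffers[[paste0(nm, ".var")]] <- rep(1, ch)
  }
  structure(list(config = config, params = p, buffers = buffers),
            class = "crop_network")
}

#' @export
print.crop_network <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, 1L))
  cat(sprintf(
    "<crop_network> depth %d, base %d channels, %s->%s, %s parameters\n",
    cfg$depth, cfg$base_channels, cfg$in_channels, cfg$out_channels,
    format(n_par, big.mark = ",")))
  s <- network_summary(cfg)
  cat(sprintf("  nominal input %dpx, bottleneck side %d\n",
              cfg$input_side, as.integer(s$bottleneck_side)))
  invisible(x)
}

# Promote [H,W,C] to [H,W,C,1].
.as_batch <- function(x) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  x
}

.check_input <- function(net, x) {
  d <- dim(x)
  if (length(d) != 4) stop("input must be an [H, W, C, N] array")
  if (d[3] != net$config$in_channels)
    stop(sprintf("input has %d channels, network expects %d", d[3],
                 net$config$in_channels))
  f <- 2^net$config$depth
  if (d[1] %% f != 0 || d[2] %% f != 0)
    stop(sprintf("input side (%d x %d) must be divisible by 2^depth = %d",
                 d[1], d[2], f))
  if (min(x) < -1e-8 || max(x) > 1 + 1e-8)
    stop("input values must lie in [0, 1]")
  invisible(TRUE)
}

# Core forward pass.  Returns list(prob, cache); cache is NULL unless kept.
net_forward <- function(net, x, train = FALSE, keep = FALSE) {
  x <- .as_batch(x)
  .check_input(net, x)
  p <- net$params
  st <- net$buffers
  depth <- net$config$depth
  cache <- if (keep) new.env(parent = emptyenv()) else NULL

  unit <- function(xin, name, kind, bn = TRUE, act = TRUE) {
    y <- switch(kind,
                conv3 = conv3_fwd(xin, p[[paste0(name, ".w")]], p[[paste0(name, ".b")]]),
                down = down_fwd(xin, p[[paste0(name, ".w")]], p[[paste0(name, ".b")]]),
                up = up_fwd(xin, p[[paste0(name, ".w")]], p[[paste0(name, ".b")]]))
    if (bn) {
      r <- bnrelu_fwd(y, p[[paste0(name, ".gamma")]], p[[paste0(name, ".beta")]],
                      st[[paste0(name, ".mean")]], st[[paste0(name, ".var")]],
                      train, 0.1, 1e-5, act)
      if (train) {
        st[[paste0(name, ".mean")]] <- r$rmean
        st[[paste0(name, ".var")]] <- r$rvar
      }
      if (keep) cache[[name]] <- list(x = xin, conv = y, mean = r$mean,
                                      invstd = r$invstd, y = r$y)
      r$y
    } else {
      out <- if (act) relu_fwd(y) else y
      if (keep) cache[[name]] <- list(x = xin, pre = y)
      out
    }
  }

  s0 <- unit(unit(x, "stem1", "conv3"), "stem2", "conv3")
  enc_out <- vector("list", depth)
  cur <- s0
  for (d in seq_len(depth)) {
    cur <- unit(cur, paste0("enc", d, ".down"), "down")
    cur <- unit(cur, paste0("enc", d, ".a"), "conv3")
    cur <- unit(cur, paste0("enc", d, ".b"), "conv3")
    enc_out[[d]] <- cur
  }
  for (d in rev(seq_len(depth))) {
    u <- unit(cur, paste0("dec", d, ".up"), "up")
    skip <- if (d == 1) s0 else enc_out[[d - 1]]
    du <- dim(u)
    cur <- array(0, dim = c(du[1], du[2], 2 * du[3], du[4]))
    cur[, , seq_len(du[3]), ] <- skip
    cur[, , du[3] + seq_len(du[3]), ] <- u
    if (d > 1) {
      cur <- unit(cur, paste0("dec", d, ".a"), "conv3")
      cur <- unit(cur, paste0("dec", d, ".b"), "conv3")
    }
  }
  cur <- unit(cur, "head1", "conv3")
  cur <- unit(cur, "head2", "conv3")
  z <- unit(cur, "head3", "conv3", bn = FALSE, act = FALSE)
  prob <- sigmoid(z)
  if (keep) cache[["prob"]] <- prob
  list(prob = prob, cache = cache)
}

# Backward pass through the whole network given dL/d(prob).
# Returns the named list of parameter gradients.
net_backward <- function(net, cache, dprob) {
  p <- net$params
  depth <- net$config$depth
  grads <- new.env(parent = emptyenv())
  addg <- function(name, g) {
    grads[[name]] <- if (is.null(grads[[name]])) g else grads[[name]] + g
  }
  unit_bwd <- function(name, kind, dy, bn = TRUE, act = TRUE) {
    cc <- cache[[name]]
    if (bn) {
      r <- bnrelu_bwd(cc$conv, cc$mean, cc$invstd,
                      p[[paste0(name, ".gamma")]], cc$y, dy, act)
      addg(paste0(name, ".gamma"), r$dgamma)
      addg(paste0(name, ".beta"), r$dbeta)
      dy <- r$dx
    } else if (act) {
      dy <- relu_bwd(cc$pre, dy)
    }
    bw <- switch(kind,
                 conv3 = conv3_bwd(cc$x, p[[paste0(name, ".w")]], dy),
                 down = down_bwd(cc$x, p[[paste0(name, ".w")]], dy),
                 up = up_bwd(cc$x, p[[paste0(name, ".w")]], dy))
    addg(paste0(name, ".w"), bw$dw)
    addg(paste0(name, ".b"), bw$db)
    bw$dx
  }

  prob <- cache[["prob"]]
  dz <- dprob * prob * (1 - prob)
  g <- unit_bwd("head3", "conv3", dz, bn = FALSE, act = FALSE)
  g <- unit_bwd("head2", "conv3", g)
  g <- unit_bwd("head1", "conv3", g)

  skip_grads <- vector("list", depth)  # slot d = grad wrt enc_out[[d]]
  dstem <- NULL
  for (d in seq_len(depth)) {  # reverse of the decoder's depth..1 order
    if (d > 1) {
      g <- unit_bwd(paste0("dec", d, ".b"), "conv3", g)
      g <- unit_bwd(paste0("dec", d, ".a"), "conv3", g)
    }
    cu <- dim(g)[3] / 2
    dskip <- g[, , seq_len(cu), , drop = FALSE]
    du <- g[, , cu + seq_len(cu), , drop = FALSE]
    if (d == 1) dstem <- dskip else skip_grads[[d - 1]] <- dskip
    g <- unit_bwd(paste0("dec", d, ".up"), "up", du)
  }
  for (d in rev(seq_len(depth))) {
    if (d < depth) g <- g + skip_grads[[d]]
    g <- unit_bwd(paste0("enc", d, ".b"), "conv3", g)
    g <- unit_bwd(paste0("enc", d, ".a"), "conv3", g)
    g <- unit_bwd(paste0("enc", d, ".down"), "down", g)
  }
  if (depth > 0) g <- g + dstem
  g <- unit_bwd("stem2", "conv3", g)
  unit_bwd("stem1", "conv3", g)
  as.list(grads)
}

#' Run a network on a batch of images
#'
#' @param network A [build_network()] object.
#' @param batch An `[H, W, C]` image or `[H, W, C, N]` batch with values in
#'   `[0, 1]` and spatial sides divisible by `2^depth`.
#' @return An `[H, W, 1, N]` array of per-pixel probabilities in `(0, 1)`.
#' @export
forward <- function(network, batch) {
  stopifnot(inherits(network, "crop_network"))
  net_forward(network, batch, train = FALSE, keep = FALSE)$prob
}

#' Save / load a network checkpoint
#'
#' A checkpoint is a single serialized weight container (`.rds`) plus a JSON
#' sidecar recording the configuration and, when given, the epoch and
#' validation IoU (also embedded in the filename).
#'
#' @param network A `crop_network`.
#' @param dir Directory to write into (created if needed).
#' @param epoch,iou Optional epoch index and validation IoU.
#' @param prefix Filename prefix.
#' @return Path of the written `.rds` file, invisibly.
#' @export
save_checkpoint <- function(network, dir, epoch = NULL, iou = NULL,
                            prefix = "net") {
  stopifnot(inherits(network, "crop_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- prefix
  if (!is.null(epoch)) stem <- sprintf("%s_ep%05d", stem, as.integer(epoch))
  if (!is.null(iou)) stem <- sprintf("%s_iou%.4f", stem, iou)
  path <- file.path(dir, paste0(stem, ".rds"))
  saveRDS(list(config = unclass(network$config), params = network$params,
               buffers = as.list(network$buffers)), path)
  jsonlite::write_json(
    list(config = unclass(network$config), epoch = epoch, iou = iou),
    file.path(dir, paste0(stem, ".json")), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @param path Path to a checkpoint `.rds` file.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- do.call(network_config, obj$config)
  net <- structure(list(config = cfg, params = obj$params,
                        buffers = new.env(parent = emptyenv())),
                   class = "crop_network")
  for (nm in names(obj$buffers)) net$buffers[[nm]] <- obj$buffers[[nm]]
  net
}
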