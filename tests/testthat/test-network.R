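test_that("configuration invariants are enforced with named errors", {
  expect_error(network_config(input_side = 100, depth = 3), "divisible")
  expect_error(network_config(base_channels = 0), "base_channels")
  expect_error(network_config(depth = -1), "depth")
  expect_error(network_config(depth = 2.5), "depth")
  cfg <- network_config(input_side = 64, base_channels = 8, depth = 4)
  expect_s3_class(cfg, "crop_config")
})

test_that("deep geometry: 7 downsamplings shrink a 512 input to side 4", {
  s <- network_summary(network_config(input_side = 512, depth = 7))
  expect_equal(s$bottleneck_side, 512 * 2^-7)
  expect_equal(s$bottleneck_side, 4)
  # channel doubling per encoder stage: base * 2^d
  expect_equal(s$stages$channels, c(16, 16 * 2^(1:7)))
  expect_equal(s$stages$side, c(512, 512 / 2^(1:7)))
})

test_that("output spatial dims equal input dims for depths 0 through 4", {
  for (d in 0:4) {
    net <- tiny_net(side = 32, base = 2, depth = d, seed = d + 1)
    p <- forward(net, rand_image(32, seed = d))
    expect_equal(dim(p), c(32L, 32L, 1L, 1L), info = paste("depth", d))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("the network is fully convolutional across input sizes", {
  net <- tiny_net(side = 16, base = 2, depth = 2)
  for (side in c(16, 32)) {
    p <- forward(net, rand_image(side, seed = side))
    expect_equal(dim(p)[1:2], c(side, side))
  }
  # a genuinely deep network still runs at a modest width
  net7 <- build_network(network_config(input_side = 128, base_channels = 1,
                                       depth = 7), seed = 1)
  p <- forward(net7, rand_image(128, seed = 3))
  expect_equal(dim(p)[1:2], c(128L, 128L))
})

test_that("encoder/decoder channel counts double and halve as configured", {
  cfg <- network_config(input_side = 64, base_channels = 4, depth = 3)
  net <- build_network(cfg, seed = 1)
  for (d in 1:3) {
    expect_equal(dim(net$params[[paste0("enc", d, ".down.w")]]),
                 c(2, 2, 4 * 2^(d - 1), 4 * 2^d))
    expect_equal(dim(net$params[[paste0("dec", d, ".up.w")]]),
                 c(4 * 2^d, 2, 2, 4 * 2^(d - 1)))
  }
  # head consumes the full-resolution concatenation: 2*base -> base -> base -> 1
  expect_equal(dim(net$params$head1.w), c(3, 3, 8, 4))
  expect_equal(dim(net$params$head2.w), c(3, 3, 4, 4))
  expect_equal(dim(net$params$head3.w), c(3, 3, 4, 1))
})

test_that("parameter count matches an independent layer-by-layer sum", {
  b <- 4; depth <- 3; cin <- 3
  # independent enumeration: conv w+b, plus gamma+beta per batch-norm
  conv <- function(k, ci, co) k * k * ci * co + co
  bn <- function(ch) 2 * ch
  expected <- conv(3, cin, b) + bn(b) + conv(3, b, b) + bn(b)   # stem
  for (d in 1:depth) {
    cd <- b * 2^d
    expected <- expected + conv(2, cd / 2, cd) + bn(cd) +        # downsample
      2 * (conv(3, cd, cd) + bn(cd))                             # two 3x3
    cu <- b * 2^(d - 1)
    expected <- expected + conv(2, cd, cu) + bn(cu)              # transposed
    if (d > 1)
      expected <- expected + conv(3, cd, cu) + bn(cu) +
        conv(3, cu, cu) + bn(cu)
  }
  expected <- expected + conv(3, 2 * b, b) + bn(b) +
    conv(3, b, b) + bn(b) + conv(3, b, 1)                        # head
  net <- build_network(network_config(input_side = 64, base_channels = b,
                                      depth = depth), seed = 1)
  expect_equal(sum(vapply(net$params, length, 1L)), expected)
})

test_that("forward is deterministic in evaluation mode", {
  net <- tiny_net(seed = 5)
  x <- rand_image(16, seed = 9)
  expect_identical(forward(net, x), forward(net, x))
})

test_that("invalid inputs fail before any computation", {
  net <- tiny_net(side = 16, depth = 2)
  expect_error(forward(net, rand_image(15)), "divisible")
  expect_error(forward(net, array(runif(16 * 16 * 2), c(16, 16, 2))),
               "channels")
  bad <- rand_image(16); bad[1] <- 1.5
  expect_error(forward(net, bad), "\\[0, 1\\]")
})

test_that("whole-network gradients match finite differences", {
  net <- tiny_net(side = 8, base = 2, depth = 1, seed = 2)
  set.seed(3)
  x <- array(runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  t <- array(rbinom(8 * 8 * 2, 1, 0.5), c(8, 8, 1, 2))
  lossfun <- function(params) {
    n2 <- net; n2$params <- params
    p <- cropseg:::net_forward(n2, x, train = TRUE)$prob
    (soft_dice_loss(p[, , 1, 1], t[, , 1, 1]) +
       soft_dice_loss(p[, , 1, 2], t[, , 1, 2])) / 2
  }
  fw <- cropseg:::net_forward(net, x, train = TRUE, keep = TRUE)
  dprob <- array(0, dim(fw$prob))
  for (i in 1:2) {
    s <- soft_dice_loss(fw$prob[, , 1, i], t[, , 1, i], gradient = TRUE)
    dprob[, , 1, i] <- s$grad / 2
  }
  g <- cropseg:::net_backward(net, fw$cache, dprob)
  set.seed(4)
  for (nm in c("stem1.w", "enc1.a.w", "dec1.up.w", "head3.b", "enc1.down.gamma")) {
    k <- sample(length(net$params[[nm]]), 1)
    eps <- 1e-5
    p1 <- net$params; p1[[nm]][k] <- p1[[nm]][k] + eps
    p2 <- net$params; p2[[nm]][k] <- p2[[nm]][k] - eps
    fd <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
    expect_lt(abs(fd - g[[nm]][k]), 1e-6 + 1e-3 * abs(fd), label = nm)
  }
})

test_that("checkpoints round-trip weights, buffers and config", {
  net <- tiny_net(seed = 7)
  x <- rand_image(16, seed = 1)
  dir <- withr::local_tempdir()
  path <- save_checkpoint(net, dir, epoch = 12, iou = 0.9876)
  expect_match(basename(path), "ep00012_iou0.9876")
  expect_true(file.exists(sub("rds$", "json", path)))
  net2 <- load_checkpoint(path)
  expect_identical(forward(net2, x), forward(net, x))
  side <- jsonlite::read_json(sub("rds$", "json", path))
  expect_equal(side$config$depth, 2)
})
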