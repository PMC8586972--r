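test_that("80/20 splits reproduce the reference dataset sizes", {
  cases <- list(c(172, 137, 35), c(86, 68, 18), c(10, 8, 2))
  for (cs in cases) {
    sp <- split_dataset(as.list(seq_len(cs[1])), 0.8, seed = 1)
    expect_length(sp$train, cs[2])
    expect_length(sp$validation, cs[3])
    ids <- c(unlist(sp$train), unlist(sp$validation))
    expect_setequal(ids, seq_len(cs[1]))   # disjoint and exhaustive
  }
  expect_error(split_dataset(list(1)), "at least 2")
})

test_that("evaluation scores replicates x samples pairs and a perfect
           predictor reaches IoU 1", {
  set.seed(1)
  ds <- lapply(1:7, function(i) {
    sc <- generate_scene(scene_spec(canvas_side = 32, radius = c(6, 10)),
                         seed = 40 + i)
    list(image = sc$image, mask = sc$mask)
  })
  # oracle stub: returns the ground-truth mask it is asked about
  k <- 0
  oracle <- local({
    i <- 0
    function(image) {
      i <<- (i %% 7) + 1
      ds[[i]]$mask
    }
  })
  m <- evaluate(oracle, ds, spec = NULL, replicates = 5)
  expect_equal(as.numeric(m), 1)
  expect_length(attr(m, "ious"), 35)
  # without augmentation all replicates are identical
  ious <- matrix(attr(m, "ious"), nrow = 7)
  expect_true(all(ious == ious[, 1]))
  expect_error(evaluate(oracle, list()), "empty")
})

test_that("a tiny network overfits one synthetic sample", {
  sc <- generate_scene(scene_spec(canvas_side = 64), seed = 7)
  net <- build_network(network_config(input_side = 64, base_channels = 4,
                                      depth = 3), seed = 3)
  one <- list(list(image = sc$image, mask = sc$mask))
  res <- train_loop(net, one, one,
                    train_protocol(lr = 1e-3, epochs = 200, batch_size = 1,
                                   eval_period = 20, eval_replicates = 1,
                                   seed = 5))
  expect_lt(tail(res$history$loss, 1), 0.05)
  # loss trend: the last stretch of training sits below the first
  expect_lt(median(tail(res$history$loss, 2)), median(head(res$history$loss, 2)))
  # best checkpoint is the max of the history's IoU column
  expect_equal(res$best$iou, max(res$history$iou))
  expect_true(res$history$is_best[which.max(res$history$iou)])
})

test_that("training histories are reproducible under fixed seeds", {
  ds <- lapply(1:4, function(i) {
    sc <- generate_scene(scene_spec(canvas_side = 16, radius = c(3, 5),
                                    n_distractors = 0), seed = 60 + i)
    list(image = sc$image, mask = sc$mask)
  })
  run <- function() {
    net <- build_network(network_config(input_side = 16, base_channels = 2,
                                        depth = 2), seed = 9)
    train_loop(net, ds[1:3], ds[4],
               train_protocol(lr = 1e-3, epochs = 4, batch_size = 2,
                              eval_period = 2, eval_replicates = 2,
                              augment = augment_spec(), seed = 17))$history
  }
  expect_identical(run(), run())
})

test_that("non-finite losses abort with a diagnostic", {
  sc <- generate_scene(scene_spec(canvas_side = 16, n_distractors = 0),
                       seed = 3)
  net <- build_network(network_config(input_side = 16, base_channels = 2,
                                      depth = 1), seed = 1)
  net$params$head3.b <- NaN   # poison the head bias
  expect_error(
    train_loop(net, list(list(image = sc$image, mask = sc$mask)),
               list(list(image = sc$image, mask = sc$mask)),
               train_protocol(epochs = 1, batch_size = 1, eval_period = 1,
                              eval_replicates = 1, seed = 1)),
    "non-finite|prediction")
})
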