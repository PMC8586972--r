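#' Training protocol
#'
#' Bundles the optimization settings: Adam with learning rate 0.001 for
#' training from scratch and 0.0001 for fine-tuning an existing checkpoint;
#' periodic validation every `eval_period` epochs, averaged over
#' `eval_replicates` independently re-augmented copies of the validation
#' set.  An epoch is one full pass over the (shuffled) training set.
#'
#' @param lr Learning rate (> 0).
#' @param epochs Number of epochs.
#' @param batch_size Mini-batch size.
#' @param eval_period Validate every this many epochs.
#' @param eval_replicates Augmented replicates per validation (>= 1).
#' @param augment An [augment_spec()] applied to training batches and (when
#'   `eval_augment` is `TRUE`) to validation replicates, or `NULL` for none.
#' @param eval_augment Apply `augment` during validation?
#' @param seed Seed for shuffling/augmentation inside the loop.
#' @param checkpoint_dir Optional directory for best-IoU checkpoints.
#' @param verbose Print progress lines?
#' @return An object of class `train_protocol`.
#' @export
train_protocol <- function(lr = 0.001, epochs = 30, batch_size = 8,
                           eval_period = 100, eval_replicates = 5,
                           augment = NULL, eval_augment = TRUE, seed = 1,
                           checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1, eval_period >= 1,
            eval_replicates >= 1)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 eval_period = as.integer(eval_period),
                 eval_replicates = as.integer(eval_replicates),
                 augment = augment, eval_augment = eval_augment,
                 seed = seed, checkpoint_dir = checkpoint_dir,
                 verbose = verbose),
            class = "train_protocol")
}

#' Random train/validation split
#'
#' The training set receives `floor(train_fraction * N)` samples drawn at
#' random; the remainder is the validation set.  The two are disjoint and
#' exhaustive.
#'
#' @param samples A list of samples.
#' @param train_fraction Fraction for the training set (default 0.8).
#' @param seed Integer seed.
#' @return `list(train, validation)`.
#' @examples
#' s <- split_dataset(as.list(1:172), seed = 1)
#' lengths(s)  # 137 and 35
#' @export
split_dataset <- function(samples, train_fraction = 0.8, seed = 1) {
  n <- length(samples)
  if (n < 2) stop("need at least 2 samples to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  set.seed(seed)
  n_train <- floor(train_fraction * n)
  idx <- sample.int(n, n_train)
  list(train = samples[idx], validation = samples[-idx])
}

# Stack a list of samples into [H,W,C,N] / [H,W,1,N] batch arrays.
.stack_samples <- function(samples) {
  d <- dim(samples[[1]]$image)
  N <- length(samples)
  x <- array(0, dim = c(d[1], d[2], d[3], N))
  t <- array(0, dim = c(d[1], d[2], 1, N))
  for (i in seq_len(N)) {
    x[, , , i] <- samples[[i]]$image
    t[, , 1, i] <- samples[[i]]$mask
  }
  list(x = x, t = t)
}

#' Evaluate mean IoU over a dataset
#'
#' For each replicate every sample is freshly augmented (when `spec` is
#' given), predicted, binarized at 0.5, and scored by IoU against its mask;
#' the grand mean over `replicates * length(dataset)` pairs is returned, so
#' 5 replicates of a 35-sample validation set score 175 pairs.
#'
#' @param network A `crop_network` (or a segmenter function taking an image
#'   and returning a mask, for oracle tests).
#' @param dataset List of `list(image, mask)` samples.
#' @param spec An [augment_spec()] or `NULL` for no augmentation.
#' @param replicates Number of augmented replicates.
#' @param threshold Binarization threshold.
#' @return Mean IoU (scalar); the per-pair values are attached as
#'   attribute `"ious"`.
#' @export
evaluate <- function(network, dataset, spec = NULL, replicates = 5,
                     threshold = 0.5) {
  if (length(dataset) == 0) stop("dataset is empty")
  ious <- numeric(0)
  for (r in seq_len(replicates)) {
    samp <- if (is.null(spec)) dataset else
      lapply(dataset, random_augment, spec = spec)
    for (s in samp) {
      pred <- if (is.function(network)) network(s$image) else
        binarize(forward(network, s$image)[, , 1, 1], threshold)
      ious <- c(ious, iou(pred, s$mask))
    }
  }
  structure(mean(ious), ious = ious)
}

#' Train a segmentation network
#'
#' Minimizes the symmetrized soft dice loss with Adam over shuffled
#' mini-batches.  Every `eval_period` epochs the validation IoU is measured
#' with [evaluate()]; whenever it exceeds the previous best the network is
#' checkpointed (ties keep the earlier epoch).  Fine-tuning is the same
#' call starting from an existing network with a reduced learning rate.
#'
#' @param network A freshly built or previously trained `crop_network`.
#' @param train_set,val_set Disjoint lists of `list(image, mask)` samples.
#' @param protocol A [train_protocol()].
#' @return `list(network, history, best)`: the final network, a history
#'   data frame (`epoch`, `loss`, `iou`, `is_best`), and
#'   `best = list(network, epoch, iou, path)`.
#' @export
train_loop <- function(network, train_set, val_set, protocol) {
  stopifnot(inherits(network, "crop_network"),
            inherits(protocol, "train_protocol"))
  if (length(train_set) == 0) stop("empty training set")
  set.seed(protocol$seed)
  opt <- adam_init(network$params)
  n <- length(train_set)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        iou = numeric(0), is_best = logical(0))
  best <- list(network = NULL, epoch = NA_integer_, iou = -Inf, path = NULL)
  for (ep in seq_len(protocol$epochs)) {
    ord <- sample.int(n)
    ep_losses <- numeric(0)
    for (start in seq(1, n, by = protocol$batch_size)) {
      idx <- ord[start:min(start + protocol$batch_size - 1, n)]
      samp <- train_set[idx]
      if (!is.null(protocol$augment))
        samp <- lapply(samp, random_augment, spec = protocol$augment)
      b <- .stack_samples(samp)
      fw <- net_forward(network, b$x, train = TRUE, keep = TRUE)
      nb <- dim(b$x)[4]
      loss <- 0
      dprob <- array(0, dim = dim(fw$prob))
      for (i in seq_len(nb)) {
        sl <- soft_dice_loss(fw$prob[, , 1, i], b$t[, , 1, i],
                             gradient = TRUE)
        loss <- loss + sl$loss / nb
        dprob[, , 1, i] <- sl$grad / nb
      }
      if (!is.finite(loss))
        stop(sprintf("training diverged: non-finite loss at epoch %d", ep))
      grads <- net_backward(network, fw$cache, dprob)
      upd <- adam_step(network$params, grads, opt, protocol$lr)
      network$params <- upd$params
      opt <- upd$state
      ep_losses <- c(ep_losses, loss)
    }
    if (ep %% protocol$eval_period == 0 || ep == protocol$epochs) {
      miou <- as.numeric(evaluate(
        network, val_set,
        spec = if (isTRUE(protocol$eval_augment)) protocol$augment,
        replicates = protocol$eval_replicates))
      is_best <- miou > best$iou
      if (is_best) {
        best$network <- network
        best$epoch <- ep
        best$iou <- miou
        if (!is.null(protocol$checkpoint_dir))
          best$path <- save_checkpoint(network, protocol$checkpoint_dir,
                                       epoch = ep, iou = miou)
      }
      history <- rbind(history,
                       data.frame(epoch = ep, loss = mean(ep_losses),
                                  iou = miou, is_best = is_best))
      if (isTRUE(protocol$verbose))
        message(sprintf("epoch %4d  loss %.4f  val IoU %.4f%s", ep,
                        mean(ep_losses), miou, if (is_best) " *" else ""))
    }
  }
  list(network = network, history = history, best = best)
}

#' Write a training history to CSV
#'
#' @param history The history data frame from [train_loop()].
#' @param path Output CSV path.
#' @export
write_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
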