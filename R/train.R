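#' Training configuration
#'
#' Defaults mirror the reference training regime for whole-slide smear
#' segmentation: 500 epochs of minibatch-1 stochastic gradient descent at a
#' constant initial learning rate of 1e-3 with momentum 0.9.
#'
#' @param epochs Number of passes over the training split (>= 1).
#' @param batch_size Minibatch size (>= 1); gradients are averaged over the
#'   batch.
#' @param initial_lr Initial (and, here, constant) learning rate, > 0.
#' @param momentum SGD momentum coefficient.
#' @param seed Seed controlling shuffling (and nothing else).
#' @param class_weighting `"none"` or `"median_frequency"`; the latter
#'   weights the cross-entropy by median class frequency over class
#'   frequency, counteracting the extreme RBC/platelet imbalance.
#' @param checkpoint_every Save a checkpoint every this many epochs into
#'   the training output dir (0 = never).
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 500L, batch_size = 1L, initial_lr = 1e-3,
                         momentum = 0.9, seed = 1L,
                         class_weighting = c("none", "median_frequency"),
                         checkpoint_every = 0L) {
  class_weighting <- match.arg(class_weighting)
  if (epochs < 1 || batch_size < 1 || initial_lr <= 0) {
    stop_hemaseg("hemaseg_invalid_argument",
                 "need epochs >= 1, batch_size >= 1, initial_lr > 0")
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, momentum = momentum,
                 seed = as.integer(seed), class_weighting = class_weighting,
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "train_config")
}

#' Iterations per epoch
#'
#' `ceiling(n_train / batch_size)`: a trailing short batch still counts as
#' one iteration. With 103 training images at batch size 1 this is 103.
#'
#' @param n_train Number of training records (>= 1).
#' @param batch_size Minibatch size (>= 1).
#' @return Integer iteration count.
#' @export
iterations_per_epoch <- function(n_train, batch_size) {
  if (n_train < 1 || batch_size < 1) {
    stop_hemaseg("hemaseg_invalid_argument",
                 "n_train and batch_size must be >= 1")
  }
  as.integer(ceiling(n_train / batch_size))
}

median_frequency_weights <- function(pairs, n_classes) {
  counts <- numeric(n_classes)
  for (p in pairs) {
    tab <- tabulate(p$label + 1L, nbins = n_classes)
    counts <- counts + tab
  }
  freq <- counts / sum(counts)
  present <- freq > 0
  w <- numeric(n_classes)
  w[present] <- stats::median(freq[present]) / freq[present]
  w
}

#' Train a segmentation model
#'
#' Minimizes per-pixel softmax cross-entropy with SGD + momentum, minibatch
#' by minibatch, reshuffling the training order every epoch (deterministic
#' for a fixed config seed). Each iteration is logged with its minibatch
#' pixel accuracy (background included) and loss.
#'
#' @param model A `dced_model` from [build_network()].
#' @param datastore Datastore index with a `"train"` split (see
#'   [split_datastore()]), or a list of `list(image=, label=)` pairs
#'   already at the network input size.
#' @param config A [train_config()].
#' @param out_dir Optional directory for periodic checkpoints.
#' @return List of class `train_result`: `model` (trained), `log`
#'   (per-iteration data frame), `epoch_summary`.
#' @export
train_model <- function(model, datastore, config, out_dir = NULL) {
  stopifnot(inherits(model, "dced_model"), inherits(config, "train_config"))
  pairs <- if (is.data.frame(datastore)) {
    load_split(datastore, "train", model$spec$input_size)
  } else {
    datastore
  }
  n <- length(pairs)
  if (n == 0L) {
    stop_hemaseg("hemaseg_no_data", "training split is empty")
  }
  weights <- if (config$class_weighting == "median_frequency") {
    median_frequency_weights(pairs, model$spec$n_classes)
  } else NULL

  ipe <- iterations_per_epoch(n, config$batch_size)
  total <- config$epochs * ipe
  log <- data.frame(iteration = integer(total), epoch = integer(total),
                    accuracy = numeric(total), loss = numeric(total))
  velocity <- lapply(model$layers, function(l) {
    if (l$type == "conv") list(W = array(0, dim(l$W)), b = numeric(length(l$b)))
  })

  it <- 0L
  orders <- with_seed(config$seed,
                      lapply(seq_len(config$epochs), function(e) sample.int(n)))
  for (epoch in seq_len(config$epochs)) {
    ord <- orders[[epoch]]
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (b in batches) {
      acc_g <- NULL; loss <- 0; acc <- 0
      for (j in b) {
        res <- model_grad(model, pairs[[j]]$image, pairs[[j]]$label, weights)
        if (!is.finite(res$loss)) {
          stop_hemaseg("hemaseg_divergence",
                       "non-finite loss at epoch %d (lr too high?)", epoch)
        }
        loss <- loss + res$loss / length(b)
        acc <- acc + res$accuracy / length(b)
        acc_g <- accumulate_grads(acc_g, res$grads, 1 / length(b))
      }
      for (l in seq_along(model$layers)) {
        if (is.null(acc_g[[l]])) next
        velocity[[l]]$W <- config$momentum * velocity[[l]]$W -
          config$initial_lr * acc_g[[l]]$W
        velocity[[l]]$b <- config$momentum * velocity[[l]]$b -
          config$initial_lr * acc_g[[l]]$b
        model$layers[[l]]$W <- model$layers[[l]]$W + velocity[[l]]$W
        model$layers[[l]]$b <- model$layers[[l]]$b + velocity[[l]]$b
      }
      it <- it + 1L
      log$iteration[it] <- it
      log$epoch[it] <- epoch
      log$accuracy[it] <- 100 * acc
      log$loss[it] <- loss
    }
    if (!is.null(out_dir) && config$checkpoint_every > 0L &&
        epoch %% config$checkpoint_every == 0L) {
      save_checkpoint(model, file.path(out_dir,
                                       sprintf("checkpoint_ep%04d.rds", epoch)))
    }
  }
  epoch_summary <- stats::aggregate(cbind(accuracy, loss) ~ epoch, data = log,
                                    FUN = mean)
  structure(list(model = model, log = log, epoch_summary = epoch_summary),
            class = "train_result")
}

accumulate_grads <- function(acc, grads, scale) {
  if (is.null(acc)) {
    return(lapply(grads, function(g) {
      if (is.null(g)) NULL else list(W = g$W * scale, b = g$b * scale)
    }))
  }
  for (l in seq_along(grads)) {
    if (is.null(grads[[l]])) next
    acc[[l]]$W <- acc[[l]]$W + grads[[l]]$W * scale
    acc[[l]]$b <- acc[[l]]$b + grads[[l]]$b * scale
  }
  acc
}

#' Write a training log to CSV
#'
#' @param result A `train_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_train_log <- function(result, path) {
  utils::write.csv(result$log, path, row.names = FALSE)
  invisible(path)
}

#' Plot accuracy and loss curves
#'
#' Accuracy-vs-epoch and loss-vs-epoch (or per-iteration) curves as a PNG.
#'
#' @param result A `train_result`.
#' @param path Output PNG path.
#' @param by `"epoch"` or `"iteration"`.
#' @return `path`, invisibly.
#' @export
plot_training <- function(result, path, by = c("epoch", "iteration")) {
  by <- match.arg(by)
  df <- if (by == "epoch") result$epoch_summary else result$log
  x <- df[[by]]
  grDevices::png(path, width = 900, height = 420)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(1, 2))
  graphics::plot(x, df$accuracy, type = "l", xlab = by,
                 ylab = "accuracy (%)", main = "Accuracy")
  graphics::plot(x, df$loss, type = "l", xlab = by,
                 ylab = "loss", main = "Loss")
  invisible(path)
}
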