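# Training protocol: mini-batch SGD with momentum and weight decay, cosine
# annealed learning rate, cross-entropy objective, best-checkpoint retention.

#' Cosine-annealed learning rate
#'
#' \eqn{lr(t) = lr_{min} + (lr_0 - lr_{min}) (1 + cos(\pi t / T)) / 2} for
#' epoch index `t` in `[0, T]`: starts at `lr0`, reaches `lr_min` exactly at
#' `t = T`, monotonically decreasing in between.
#'
#' @param t epoch index (0-based), `0 <= t <= T`.
#' @param T total number of epochs in the cycle.
#' @param lr0 initial learning rate (default 0.01).
#' @param lr_min annealing floor (default 1e-9).
#' @return the learning rate at epoch `t`.
#' @examples
#' cosine_lr(0, 60)  # 0.01
#' cosine_lr(60, 60) # 1e-9
#' @export
cosine_lr <- function(t, T, lr0 = 0.01, lr_min = 1e-9) {
  if (any(t < 0) || any(t > T)) stop("epoch index must lie in [0, T]")
  if (lr_min >= lr0) stop("lr_min must be below lr0")
  lr_min + (lr0 - lr_min) * (1 + cos(pi * t / T)) / 2
}

#' Training configuration
#'
#' Defaults follow the standard recipe for this architecture family: batch
#' size 32, 60 epochs, SGD momentum 0.9, weight decay 5e-4, initial learning
#' rate 0.01 cosine-annealed to 1e-9.  Weight decay applies to convolution
#' and linear weights only, never to batch-norm parameters or biases.  Input
#' images (0-255 scale) are normalised per channel with the fixed constants
#' recorded here.
#'
#' @param batch_size images per optimisation step.
#' @param epochs total training passes.
#' @param lr0,lr_min initial and floor learning rate of the cosine schedule.
#' @param momentum SGD momentum coefficient.
#' @param weight_decay L2 coefficient on conv/linear weights.
#' @param seed integer seed controlling initialisation, shuffling and any
#'   augmentation randomness.
#' @param norm_mean,norm_sd per-channel normalisation constants on the 0-255
#'   scale.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, epochs = 60L, lr0 = 0.01,
                         lr_min = 1e-9, momentum = 0.9, weight_decay = 5e-4,
                         seed = 1L,
                         norm_mean = c(127.5, 127.5, 127.5),
                         norm_sd = c(60, 60, 60)) {
  stopifnot(batch_size >= 1L, epochs >= 1L, lr_min < lr0, momentum >= 0,
            weight_decay >= 0)
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 lr0 = lr0, lr_min = lr_min, momentum = momentum,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 norm_mean = norm_mean, norm_sd = norm_sd),
            class = "train_config")
}

decay_flags <- function(mod) {
  switch(mod$type,
    conv = list(w = TRUE),
    dwconv = list(w = TRUE),
    linear = list(W = TRUE, b = FALSE),
    bn = list(gamma = FALSE, beta = FALSE),
    attention = {
      if (is.null(mod$par)) list() else
        stats::setNames(as.list(rep(TRUE, length(mod$par))), names(mod$par))
    },
    list())
}

sgd_update <- function(mod, g, vel, lr, momentum, weight_decay) {
  if (is.null(g)) return(list(mod = mod, vel = vel))
  if (is.null(vel)) vel <- list()
  if (!is.null(mod$par) && !is.null(g$par)) {
    if (is.null(vel$par)) vel$par <- lapply(g$par, function(p) p * 0)
    dm <- decay_flags(mod)
    for (nm in names(g$par)) {
      gr <- g$par[[nm]]
      if (isTRUE(dm[[nm]]) && weight_decay > 0)
        gr <- gr + weight_decay * mod$par[[nm]]
      vel$par[[nm]] <- momentum * vel$par[[nm]] + gr
      mod$par[[nm]] <- mod$par[[nm]] - lr * vel$par[[nm]]
    }
  }
  if (!is.null(mod$children) && !is.null(g$children)) {
    if (is.null(vel$children)) vel$children <- vector("list", length(mod$children))
    for (i in seq_along(mod$children)) {
      r <- sgd_update(mod$children[[i]], g$children[[i]], vel$children[[i]],
                      lr, momentum, weight_decay)
      mod$children[[i]] <- r$mod
      vel$children[i] <- list(r$vel)   # [[<- would drop NULL velocities
    }
  }
  for (nm in composite_child_names(mod)) {
    r <- sgd_update(mod[[nm]], g[[nm]], vel[[nm]], lr, momentum, weight_decay)
    mod[[nm]] <- r$mod
    vel[nm] <- list(r$vel)
  }
  list(mod = mod, vel = vel)
}

# buffers (batch-norm running stats) walk, for checkpointing
buf_tree <- function(mod) {
  out <- list()
  if (!is.null(mod$buf)) out$buf <- mod$buf
  if (!is.null(mod$children)) out$children <- lapply(mod$children, buf_tree)
  for (nm in composite_child_names(mod)) out[[nm]] <- buf_tree(mod[[nm]])
  out
}

set_buf_tree <- function(mod, tree) {
  if (!is.null(tree$buf)) mod$buf <- tree$buf
  if (!is.null(mod$children))
    for (i in seq_along(mod$children))
      mod$children[[i]] <- set_buf_tree(mod$children[[i]], tree$children[[i]])
  for (nm in composite_child_names(mod)) mod[[nm]] <- set_buf_tree(mod[[nm]], tree[[nm]])
  mod
}

#' Save / restore a model checkpoint
#'
#' A checkpoint captures all trainable parameters and batch-norm running
#' statistics; restoring it onto a structurally identical model reproduces
#' its predictions bit for bit.
#'
#' @param model a `leafcnn_model`.
#' @param ckpt a checkpoint from `model_checkpoint()`.
#' @return `model_checkpoint()`: a list with `par` and `buf` trees;
#'   `restore_checkpoint()`: the model with weights restored.
#' @export
model_checkpoint <- function(model) {
  list(par = par_tree(model), buf = buf_tree(model))
}

#' @rdname model_checkpoint
#' @export
restore_checkpoint <- function(model, ckpt) {
  model <- set_par_tree(model, ckpt$par)
  set_buf_tree(model, ckpt$buf)
}

cross_entropy <- function(logits, y) {
  K <- nrow(logits); N <- ncol(logits)
  if (any(y < 1L) || any(y > K)) stop("label out of range")
  p <- softmax_probs(logits)
  idx <- cbind(y, seq_len(N))
  p_true <- p[cbind(y, seq_len(N))]
  loss <- -mean(log(pmax(p_true, 1e-12)))
  grad <- p
  grad[idx] <- grad[idx] - 1
  list(loss = loss, grad = grad / N)
}

normalize_images <- function(x, cfg) (x - cfg$norm_mean) / cfg$norm_sd

#' Train a classifier
#'
#' Runs mini-batch SGD with momentum over the training set, evaluating on
#' the test set after every epoch and retaining the weights of the
#' best-accuracy epoch.  Fully reproducible under `cfg$seed`.
#'
#' @param model a freshly built `leafcnn_model` (see [build_model()]).
#' @param train_set,test_set datasets as produced by [generate_dataset()] or
#'   [load_image_folder()]: lists with `x` (array `c(3, H, W, N)`, 0-255
#'   scale) and `y` (integer labels starting at 1).
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return object of class `train_history`: `history` (data frame of epoch,
#'   lr, train loss, test accuracy), `best_epoch`, `best_accuracy`,
#'   `best_model` (weights of the best epoch) and `model` (final weights).
#' @export
train <- function(model, train_set, test_set, cfg = train_config(),
                  verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  if (length(train_set$y) == 0L || length(test_set$y) == 0L)
    stop("empty dataset")
  K <- model$cfg$num_classes
  if (any(train_set$y > K) || any(test_set$y > K) ||
      any(train_set$y < 1L) || any(test_set$y < 1L))
    stop("label out of range for the model's class count")
  set.seed(cfg$seed)
  xtr <- normalize_images(train_set$x, cfg)
  n <- length(train_set$y)
  vel <- NULL
  hist_rows <- vector("list", cfg$epochs)
  best_acc <- -Inf; best_epoch <- NA_integer_; best_ckpt <- NULL
  for (epoch in seq_len(cfg$epochs)) {
    t <- epoch - 1L
    lr <- cosine_lr(t, cfg$epochs, cfg$lr0, cfg$lr_min)
    idx <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = cfg$batch_size)) {
      bidx <- idx[start:min(start + cfg$batch_size - 1L, n)]
      xb <- xtr[, , , bidx, drop = FALSE]
      yb <- train_set$y[bidx]
      fw <- nn_forward(model, xb, training = TRUE)
      model <- fw$mod
      ce <- cross_entropy(fw$y, yb)
      losses <- c(losses, ce$loss)
      bw <- nn_backward(model, fw$cache, ce$grad)
      up <- sgd_update(model, bw$gpar, vel, lr, cfg$momentum, cfg$weight_decay)
      model <- up$mod
      vel <- up$vel
    }
    # early epochs routinely leave classes unpredicted; the 0/0 warning is
    # expected there and only the accuracy is consumed
    ev <- suppressWarnings(evaluate(model, test_set, cfg = cfg))
    acc <- ev$report$accuracy
    hist_rows[[epoch]] <- data.frame(epoch = t, lr = lr,
                                     train_loss = mean(losses),
                                     test_accuracy = acc)
    if (acc > best_acc) {
      best_acc <- acc
      best_epoch <- t
      best_ckpt <- model_checkpoint(model)
    }
    if (verbose)
      message(sprintf("epoch %2d  lr %.6f  loss %.4f  acc %.4f",
                      t, lr, mean(losses), acc))
  }
  history <- do.call(rbind, hist_rows)
  best_model <- restore_checkpoint(model, best_ckpt)
  class(best_model) <- class(model)
  best_model$cfg <- model$cfg
  structure(list(history = history, best_epoch = best_epoch,
                 best_accuracy = best_acc, best_model = best_model,
                 model = model),
            class = "train_history")
}

#' Evaluate a model on a labelled dataset
#'
#' Predicts by argmax over softmax probabilities (evaluation mode: frozen
#' batch-norm statistics) and returns the full metrics report plus the raw
#' predictions.
#'
#' @param model a `leafcnn_model`.
#' @param dataset list with `x` and `y` as in [train()].
#' @param cfg a [train_config()] (only the normalisation constants are
#'   used).
#' @param batch_size evaluation batch size.
#' @param groups optional class-to-group map for per-crop aggregation,
#'   passed to [metrics_from_confusion()].
#' @return list with `report` (a `metrics_report`) and `predictions`.
#' @export
evaluate <- function(model, dataset, cfg = train_config(), batch_size = 64L,
                     groups = NULL) {
  n <- length(dataset$y)
  if (n == 0L) stop("empty test set")
  x <- normalize_images(dataset$x, cfg)
  K <- model$cfg$num_classes
  preds <- integer(n)
  for (start in seq(1L, n, by = batch_size)) {
    bidx <- start:min(start + batch_size - 1L, n)
    fw <- nn_forward(model, x[, , , bidx, drop = FALSE], training = FALSE)
    p <- softmax_probs(fw$y)
    preds[bidx] <- max.col(t(p), ties.method = "first")
  }
  M <- confusion_matrix(dataset$y, preds, K)
  report <- metrics_from_confusion(M, groups = groups)
  list(report = report, predictions = preds)
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("trained %d epochs; best test accuracy %.4f at epoch %d\n",
              nrow(x$history), x$best_accuracy, x$best_epoch))
  invisible(x)
}
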