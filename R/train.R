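#' Training configuration for the decoder
#'
#' Defaults follow the interface's training recipe: plain stochastic gradient
#' descent, batch size 32, initial learning rate 0.2 under cosine annealing
#' with warm restarts, 500 epochs, and additive-noise augmentation applied to
#' a random half of the samples in each batch.
#'
#' @param epochs Training epochs (default 500).
#' @param batch_size Mini-batch size (default 32).
#' @param lr0 Initial learning rate (default 0.2).
#' @param restart_period First cosine cycle length in epochs (default 50).
#' @param restart_mult Cycle-length multiplier after each warm restart
#'   (default 2).
#' @param momentum SGD momentum (default 0, plain SGD).
#' @param augment_fraction Fraction of samples receiving additive noise
#'   (default 0.5).
#' @param augment_noise_scale Noise standard deviation in microvolts; `NULL`
#'   (default) uses 10% of the per-batch RMS.
#' @param seed Seed controlling shuffling, augmentation and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 500L, batch_size = 32L, lr0 = 0.2,
                         restart_period = 50L, restart_mult = 2,
                         momentum = 0, augment_fraction = 0.5,
                         augment_noise_scale = NULL, seed = 1L) {
  if (augment_fraction < 0 || augment_fraction > 1) {
    stop("augment_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(as.list(environment()), class = "train_config")
}

#' Cosine-annealing learning rate with warm restarts
#'
#' @param epoch 0-based epoch index.
#' @param config A [train_config()].
#' @return Learning rate at that epoch; `cosine_lr(0, config)` equals
#'   `config$lr0`.
#' @export
cosine_lr <- function(epoch, config = train_config()) {
  vapply(epoch, function(e) {
    t_i <- config$restart_period
    t_cur <- e
    while (t_cur >= t_i) {
      t_cur <- t_cur - t_i
      t_i <- t_i * config$restart_mult
    }
    config$lr0 * 0.5 * (1 + cos(pi * t_cur / t_i))
  }, numeric(1))
}

#' Additive-noise augmentation of a batch
#'
#' An independent Bernoulli(`augment_fraction`) draw selects samples; selected
#' samples receive white Gaussian noise. Labels are untouched.
#'
#' @param batch Array `(batch, 1, channels, time_steps)` (labels attribute,
#'   if any, is preserved).
#' @param config A [train_config()].
#' @return The augmented batch with attribute `augmented` (logical mask).
#' @export
augment <- function(batch, config = train_config()) {
  n <- dim(batch)[1]
  if (n == 0L) stop("batch is empty", call. = FALSE)
  sel <- stats::runif(n) < config$augment_fraction
  scale <- config$augment_noise_scale
  if (is.null(scale)) scale <- 0.1 * sqrt(mean(batch^2))
  if (any(sel) && scale > 0) {
    per_trial <- prod(dim(batch)[-1])
    noise <- stats::rnorm(sum(sel) * per_trial, 0, scale)
    batch[sel, , , ] <- batch[sel, , , ] + noise
  }
  attr(batch, "augmented") <- sel
  batch
}

sgd_step <- function(params, grads, velocity, lr, momentum) {
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) {
      g <- grads[[nm]][[f]]
      if (momentum > 0) {
        v <- momentum * velocity[[nm]][[f]] + g
        velocity[[nm]][[f]] <- v
        g <- v
      }
      params[[nm]][[f]] <- params[[nm]][[f]] - lr * g
    }
  }
  list(params = params, velocity = velocity)
}

#' Train the dual-branch decoder
#'
#' Mini-batch SGD with cosine-annealing warm restarts from `lr0`; the data
#' order is reshuffled every epoch, and augmentation noise is injected into
#' a random fraction of each batch. All randomness derives from
#' `train_cfg$seed`, so identical seeds give identical training runs.
#'
#' @param model A [build_decoder()] result.
#' @param tensor Labelled trial tensor from [to_tensor()] (preprocessed).
#' @param train_cfg A [train_config()].
#' @param val_tensor Optional labelled tensor evaluated once per epoch.
#' @param verbose Print per-epoch progress every `verbose` epochs (0 = quiet).
#' @return The trained `trained_decoder`; `$history` holds one row per epoch
#'   (`epoch`, `lr`, `loss`, `train_acc`, `val_acc`).
#' @export
train_decoder <- function(model, tensor, train_cfg = train_config(),
                          val_tensor = NULL, verbose = 0L) {
  labels <- attr(tensor, "labels")
  if (is.null(labels) || dim(tensor)[1] == 0L) {
    stop("training tensor must be non-empty and labelled", call. = FALSE)
  }
  cfg <- model$config
  n <- dim(tensor)[1]
  velocity <- lapply(model$params, function(p) lapply(p, function(x) x * 0))
  hist <- vector("list", train_cfg$epochs)
  with_seed(train_cfg$seed, {
    for (epoch in seq_len(train_cfg$epochs) - 1L) {
      lr <- cosine_lr(epoch, train_cfg)
      ord <- sample.int(n)
      starts <- seq(1L, n, by = train_cfg$batch_size)
      losses <- numeric(length(starts))
      correct <- 0L
      for (s in seq_along(starts)) {
        take <- ord[starts[s]:min(starts[s] + train_cfg$batch_size - 1L, n)]
        xb <- tensor[take, , , , drop = FALSE]
        yb <- labels[take]
        xb <- augment(xb, train_cfg)
        attr(xb, "fs") <- attr(tensor, "fs")
        xt <- tensor_to_time_input(xb)
        xf <- stft_core(xb, cfg)
        fw <- decoder_forward(model, xt, xf, training = TRUE)
        for (nm in names(fw$caches$running)) {
          model$params[[nm]]$mean <- fw$caches$running[[nm]]$mean
          model$params[[nm]]$var <- fw$caches$running[[nm]]$var
        }
        sm <- softmax_xent(fw$logits, yb)
        if (!is.finite(sm$loss)) {
          stop(sprintf("divergence: non-finite loss at epoch %d", epoch),
               call. = FALSE)
        }
        losses[s] <- sm$loss
        correct <- correct +
          sum(max.col(t(fw$logits), ties.method = "first") - 1L == yb)
        grads <- decoder_backward(model, fw$caches, sm$grad)
        upd <- sgd_step(model$params, grads, velocity, lr, train_cfg$momentum)
        model$params <- upd$params
        velocity <- upd$velocity
      }
      val_acc <- NA_real_
      if (!is.null(val_tensor)) {
        pr <- predict_decoder(model, val_tensor)
        val_acc <- mean(pr$labels == attr(val_tensor, "labels"))
      }
      hist[[epoch + 1L]] <- data.frame(
        epoch = epoch, lr = lr, loss = mean(losses),
        train_acc = correct / n, val_acc = val_acc)
      if (verbose > 0L && (epoch %% verbose == 0L)) {
        message(sprintf("epoch %3d  lr %.4f  loss %.4f  acc %.3f  val %.3f",
                        epoch, lr, mean(losses), correct / n, val_acc))
      }
    }
  })
  model$history <- do.call(rbind, hist)
  model
}
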