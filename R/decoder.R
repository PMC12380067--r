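#' Configuration of the dual-branch SSVEP decoder
#'
#' The decoder processes each 1-s trial along two concurrent branches. The
#' time branch applies a stack of 2-D convolution blocks (conv -> batch norm
#' -> ReLU -> max pool) directly to the `(1, channels, time)` waveform tensor,
#' with the first kernel spanning the full channel axis, then a linear layer.
#' The frequency branch applies residual blocks with dilated convolutions
#' (kernel `dilated_kernel`, default `(9, 13)`) to the per-channel STFT
#' magnitude map, then a linear layer. Branch features are concatenated into
#' the embedding that feeds the final fully connected classifier over the
#' 8 commands.
#'
#' @param n_classes Number of output classes (8 commands).
#' @param channels,time_steps,fs Input geometry of one trial.
#' @param time_filters,time_kernels,time_pools Per-block feature maps, kernel
#'   widths and pool widths of the time branch (3 blocks by default).
#' @param time_strides Per-block temporal convolution strides (the default
#'   strides the first conv by 2; the block pools right after, so the saved
#'   resolution would be discarded anyway).
#' @param branch_dim Feature width of each branch head; the embedding passed
#'   to the classifier has `2 * branch_dim` dimensions.
#' @param stft_window,stft_hop STFT parameters in samples (250/62 keeps >= 2
#'   cycles of 8 Hz per window and 75% overlap within a 1-s trial).
#' @param freq_max_hz Highest spectrogram bin retained (matches the 4--100 Hz
#'   band-pass).
#' @param freq_filters Feature maps inside the residual blocks.
#' @param n_res_blocks Number of residual blocks (default 2).
#' @param dilated_kernel `(height, width)` of the dilated kernels.
#' @param dilation Dilation factor in both axes.
#' @param dropout Dropout rate before the classifier.
#' @param seed Seed for weight initialization.
#' @return An object of class `decoder_config`.
#' @export
decoder_config <- function(n_classes = 8L, channels = 8L, time_steps = 1000L,
                           fs = 1000, time_filters = c(8, 8, 8),
                           time_kernels = c(25, 11, 11),
                           time_pools = c(4, 4, 4),
                           time_strides = NULL, branch_dim = 32L,
                           stft_window = 250L, stft_hop = 62L,
                           freq_max_hz = 100, freq_filters = 4L,
                           n_res_blocks = 2L, dilated_kernel = c(9, 13),
                           dilation = 2L, dropout = 0.5, seed = 1L) {
  if (is.null(time_strides)) {
    time_strides <- c(2, rep(1, length(time_filters) - 1))
  }
  if (length(time_filters) != length(time_kernels) ||
      length(time_filters) != length(time_pools) ||
      length(time_filters) != length(time_strides)) {
    stop("time branch block lists must have equal length", call. = FALSE)
  }
  if (any(dilated_kernel %% 2 != 1)) {
    stop("dilated_kernel sides must be odd for same-size residual convs",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "decoder_config")
}

# shapes of the time branch after each block; errors if a block empties
time_branch_shapes <- function(config) {
  w <- config$time_steps
  h <- config$channels
  shapes <- vector("list", length(config$time_filters))
  for (i in seq_along(config$time_filters)) {
    kh <- if (i == 1L) h else 1L
    w <- (w - config$time_kernels[i]) %/% config$time_strides[i] + 1L
    h <- h - kh + 1L
    w <- w %/% config$time_pools[i]
    if (w < 1L) stop("construction error: time branch collapses; shorten kernels/pools",
                     call. = FALSE)
    shapes[[i]] <- c(w = w, h = h, kh = kh)
  }
  shapes
}

freq_map_shape <- function(config) {
  n_frames <- floor((config$time_steps - config$stft_window) /
                      config$stft_hop) + 1
  freqs <- (0:(config$stft_window %/% 2)) * config$fs / config$stft_window
  c(w = n_frames, h = sum(freqs <= config$freq_max_hz))
}

#' Build an (untrained) dual-branch decoder
#'
#' @param config A [decoder_config()].
#' @return An object of class `trained_decoder` with freshly initialized
#'   weights (He initialization, seeded), an empty training history, and the
#'   config snapshot.
#' @export
build_decoder <- function(config = decoder_config()) {
  tsh <- time_branch_shapes(config)
  fsh <- freq_map_shape(config)
  nb <- config$n_res_blocks
  ff <- config$freq_filters
  with_seed(config$seed, {
    params <- list()
    cin <- 1L
    for (i in seq_along(config$time_filters)) {
      params[[paste0("tc", i)]] <- init_conv(config$time_kernels[i],
                                             tsh[[i]]["kh"], cin,
                                             config$time_filters[i])
      params[[paste0("tb", i)]] <- init_bn(config$time_filters[i])
      cin <- config$time_filters[i]
    }
    last <- tsh[[length(tsh)]]
    params$tl <- init_linear(last["w"] * last["h"] * cin, config$branch_dim)
    if (config$channels != ff) {
      params$fstem <- init_conv(1L, 1L, config$channels, ff)
    }
    for (b in seq_len(nb)) {
      params[[paste0("fb", b, "c1")]] <- init_conv(config$dilated_kernel[2],
                                                   config$dilated_kernel[1],
                                                   ff, ff)
      params[[paste0("fb", b, "n1")]] <- init_bn(ff)
      params[[paste0("fb", b, "c2")]] <- init_conv(config$dilated_kernel[2],
                                                   config$dilated_kernel[1],
                                                   ff, ff)
      params[[paste0("fb", b, "n2")]] <- init_bn(ff)
    }
    params$fl <- init_linear(fsh["w"] * fsh["h"] * ff, config$branch_dim)
    params$head <- init_linear(2L * config$branch_dim, config$n_classes)
    structure(list(params = params, config = config,
                   history = data.frame()), class = "trained_decoder")
  })
}

#' @export
print.trained_decoder <- function(x, ...) {
  npar <- sum(vapply(unlist(x$params, recursive = FALSE), length, numeric(1)))
  cat(sprintf("<trained_decoder> %d classes, %d parameters, %d epochs trained\n",
              x$config$n_classes, npar, nrow(x$history)))
  invisible(x)
}

# public (N,1,C,T) tensor -> internal time-branch layout (W=T, H=C, C=1, N)
tensor_to_time_input <- function(tensor) {
  aperm(tensor, c(4, 3, 2, 1))
}

# public (N,C,H,W) stft map -> internal (W, H, C, N)
map_to_freq_input <- function(map) {
  aperm(map, c(4, 3, 2, 1))
}

same_pad <- function(config) {
  c(h = config$dilation * (config$dilated_kernel[1] - 1) %/% 2,
    w = config$dilation * (config$dilated_kernel[2] - 1) %/% 2)
}

# Full forward pass. xt: (T, channels, 1, N); xf: (frames, bins, channels, N).
decoder_forward <- function(model, xt, xf, training = FALSE) {
  p <- model$params
  cfg <- model$config
  caches <- list(running = list())
  x <- xt
  for (i in seq_along(cfg$time_filters)) {
    cv <- conv_fw(p[[paste0("tc", i)]], x,
                  stride = c(1, cfg$time_strides[i]))
    bn <- bn_fw(p[[paste0("tb", i)]], cv$y, training)
    if (!is.null(bn$running)) caches$running[[paste0("tb", i)]] <- bn$running
    rl <- relu_fw(bn$y)
    pl <- pool_fw(rl$y, c(1, cfg$time_pools[i]))
    caches[[paste0("t", i)]] <- list(cv = cv$cache, bn = bn$cache,
                                     rl = rl$cache, pl = pl$cache)
    x <- pl$y
  }
  tdim <- dim(x)
  dim(x) <- c(prod(tdim[1:3]), tdim[4])
  tl <- linear_fw(p$tl, x)
  trl <- relu_fw(tl$y)
  caches$tflat <- tdim; caches$tl <- tl$cache; caches$trl <- trl$cache
  tfeat <- trl$y

  pad <- same_pad(cfg)
  dil <- c(cfg$dilation, cfg$dilation)
  x <- xf
  if (!is.null(p$fstem)) {
    st <- conv_fw(p$fstem, x)
    caches$fstem <- st$cache
    x <- st$y
  }
  for (b in seq_len(cfg$n_res_blocks)) {
    iden <- x
    c1 <- conv_fw(p[[paste0("fb", b, "c1")]], x, dil = dil, pad = pad)
    n1 <- bn_fw(p[[paste0("fb", b, "n1")]], c1$y, training)
    if (!is.null(n1$running))
      caches$running[[paste0("fb", b, "n1")]] <- n1$running
    r1 <- relu_fw(n1$y)
    c2 <- conv_fw(p[[paste0("fb", b, "c2")]], r1$y, dil = dil, pad = pad)
    n2 <- bn_fw(p[[paste0("fb", b, "n2")]], c2$y, training)
    if (!is.null(n2$running))
      caches$running[[paste0("fb", b, "n2")]] <- n2$running
    rs <- relu_fw(n2$y + iden)
    caches[[paste0("f", b)]] <- list(c1 = c1$cache, n1 = n1$cache,
                                     r1 = r1$cache, c2 = c2$cache,
                                     n2 = n2$cache, rs = rs$cache)
    x <- rs$y
  }
  fdim <- dim(x)
  dim(x) <- c(prod(fdim[1:3]), fdim[4])
  fl <- linear_fw(p$fl, x)
  frl <- relu_fw(fl$y)
  caches$fflat <- fdim; caches$fl <- fl$cache; caches$frl <- frl$cache
  ffeat <- frl$y

  embed <- rbind(tfeat, ffeat)
  dp <- dropout_fw(embed, cfg$dropout, training)
  hd <- linear_fw(p$head, dp$y)
  caches$dp <- dp$cache; caches$hd <- hd$cache
  list(logits = hd$y, embed = embed, caches = caches)
}

decoder_backward <- function(model, caches, glogits) {
  p <- model$params
  cfg <- model$config
  grads <- list()
  hb <- linear_bw(p$head, caches$hd, glogits)
  grads$head <- hb$grads
  gembed <- dropout_bw(caches$dp, hb$gx)
  bd <- cfg$branch_dim
  gt <- gembed[seq_len(bd), , drop = FALSE]
  gf <- gembed[bd + seq_len(bd), , drop = FALSE]

  # frequency branch
  gf <- relu_bw(caches$frl, gf)
  fb <- linear_bw(p$fl, caches$fl, gf)
  grads$fl <- fb$grads
  gx <- fb$gx
  dim(gx) <- caches$fflat
  pad <- same_pad(cfg)
  for (b in rev(seq_len(cfg$n_res_blocks))) {
    cc <- caches[[paste0("f", b)]]
    gsum <- relu_bw(cc$rs, gx)
    n2 <- bn_bw(p[[paste0("fb", b, "n2")]], cc$n2, gsum)
    grads[[paste0("fb", b, "n2")]] <- n2$grads
    c2 <- conv_bw(p[[paste0("fb", b, "c2")]], cc$c2, n2$gx)
    grads[[paste0("fb", b, "c2")]] <- c2$grads
    g1 <- relu_bw(cc$r1, c2$gx)
    n1 <- bn_bw(p[[paste0("fb", b, "n1")]], cc$n1, g1)
    grads[[paste0("fb", b, "n1")]] <- n1$grads
    c1 <- conv_bw(p[[paste0("fb", b, "c1")]], cc$c1, n1$gx)
    grads[[paste0("fb", b, "c1")]] <- c1$grads
    gx <- c1$gx + gsum
  }
  if (!is.null(p$fstem)) {
    sb <- conv_bw(p$fstem, caches$fstem, gx)
    grads$fstem <- sb$grads
  }

  # time branch
  gt <- relu_bw(caches$trl, gt)
  tb <- linear_bw(p$tl, caches$tl, gt)
  grads$tl <- tb$grads
  gx <- tb$gx
  dim(gx) <- caches$tflat
  for (i in rev(seq_along(cfg$time_filters))) {
    cc <- caches[[paste0("t", i)]]
    gx <- pool_bw(cc$pl, gx)
    gx <- relu_bw(cc$rl, gx)
    nb <- bn_bw(p[[paste0("tb", i)]], cc$bn, gx)
    grads[[paste0("tb", i)]] <- nb$grads
    cb <- conv_bw(p[[paste0("tc", i)]], cc$cv, nb$gx)
    grads[[paste0("tc", i)]] <- cb$grads
    gx <- cb$gx
  }
  grads
}

#' Decode trials with a trained decoder
#'
#' Runs the network in evaluation mode (batch-norm running statistics, no
#' dropout), so repeated calls are bit-identical.
#'
#' @param model A [build_decoder()] / [train_decoder()] result.
#' @param tensor Array `(batch, 1, channels, time_steps)` from [to_tensor()].
#' @return List with `labels` (predicted class indices 0--7), `embeddings`
#'   (`batch x embed_dim` features before the final fully connected layer,
#'   e.g. for t-SNE) and `probs` (`batch x n_classes` softmax outputs).
#' @export
predict_decoder <- function(model, tensor) {
  cfg <- model$config
  d <- dim(tensor)
  if (length(d) != 4L || d[3] != cfg$channels || d[4] != cfg$time_steps) {
    stop(sprintf("tensor shape (%s) does not match decoder config (*, 1, %d, %d)",
                 paste(d, collapse = ", "), cfg$channels, cfg$time_steps),
         call. = FALSE)
  }
  xt <- tensor_to_time_input(tensor)
  xf <- stft_core(tensor, cfg)
  fw <- decoder_forward(model, xt, xf, training = FALSE)
  sm <- softmax_xent(fw$logits, integer(ncol(fw$logits)))
  list(labels = max.col(t(fw$logits), ties.method = "first") - 1L,
       embeddings = t(fw$embed),
       probs = t(sm$probs))
}

#' @rdname predict_decoder
#' @param object,... S3 method arguments (`newdata` passed on as `tensor`).
#' @param newdata Trial tensor to decode.
#' @export
predict.trained_decoder <- function(object, newdata, ...) {
  predict_decoder(object, newdata)
}
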