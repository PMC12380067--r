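# Neural-network primitives for the dual-branch decoder.
#
# Activations are column-major arrays (W, H, C, N): W = time samples or
# spectrogram frames (fastest axis), H = montage channels or frequency bins,
# C = feature maps, N = batch. Convolution/pooling kernels live in src/;
# batch norm, dropout and linear layers are plain R. Every forward returns
# list(y, cache) and every backward returns list(gx, grads) so the training
# loop stays an explicit, testable chain.

expand_channel <- function(v, d) {
  # per-feature-map vector -> full (W,H,C,N) array layout
  rep(rep(v, each = d[1] * d[2]), times = d[4])
}

init_conv <- function(kw, kh, cin, cout) {
  fan_in <- kw * kh * cin
  list(w = array(stats::rnorm(kw * kh * cin * cout, 0, sqrt(2 / fan_in)),
                 dim = c(kw, kh, cin, cout)),
       b = numeric(cout))
}

init_bn <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       mean = numeric(c), var = rep(1, c))
}

init_linear <- function(din, dout) {
  list(w = matrix(stats::rnorm(dout * din, 0, sqrt(2 / din)), dout, din),
       b = numeric(dout))
}

conv_fw <- function(p, x, dil = c(1, 1), pad = c(0, 0), stride = c(1, 1)) {
  y <- conv2d_fw(x, p$w, p$b, dil[1], dil[2], pad[1], pad[2],
                 stride[1], stride[2])
  list(y = y, cache = list(x = x, dil = dil, pad = pad, stride = stride))
}

conv_bw <- function(p, cache, gy) {
  g <- conv2d_bw(cache$x, p$w, gy, cache$dil[1], cache$dil[2],
                 cache$pad[1], cache$pad[2], cache$stride[1], cache$stride[2])
  list(gx = g$gx, grads = list(w = g$gw, b = g$gb))
}

bn_fw <- function(p, x, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  m <- d[1] * d[2] * d[4]
  if (training) {
    xm <- matrix(x, nrow = d[1] * d[2])           # cols enumerate (c, n)
    cs <- matrix(.colSums(xm, nrow(xm), ncol(xm)), d[3])
    ss <- matrix(.colSums(xm * xm, nrow(xm), ncol(xm)), d[3])
    mu <- rowSums(cs) / m
    v <- pmax(rowSums(ss) / m - mu^2, 0)
    upd <- list(mean = (1 - momentum) * p$mean + momentum * mu,
                var = (1 - momentum) * p$var + momentum * v)
  } else {
    mu <- p$mean; v <- p$var; upd <- NULL
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (x - expand_channel(mu, d)) * expand_channel(inv, d)
  y <- xhat * expand_channel(p$gamma, d) + expand_channel(p$beta, d)
  list(y = y, cache = list(xhat = xhat, inv = inv, d = d, m = m),
       running = upd)
}

bn_bw <- function(p, cache, gy) {
  d <- cache$d; m <- cache$m
  per_c <- function(a) {
    am <- matrix(a, nrow = d[1] * d[2])
    rowSums(matrix(.colSums(am, nrow(am), ncol(am)), d[3]))
  }
  ggamma <- per_c(gy * cache$xhat)
  gbeta <- per_c(gy)
  gxhat <- gy * expand_channel(p$gamma, d)
  s1 <- per_c(gxhat)
  s2 <- per_c(gxhat * cache$xhat)
  gx <- expand_channel(cache$inv / m, d) *
    (m * gxhat - expand_channel(s1, d) - cache$xhat * expand_channel(s2, d))
  dim(gx) <- d
  list(gx = gx, grads = list(gamma = ggamma, beta = gbeta))
}

relu_fw <- function(x) {
  mask <- x > 0
  list(y = x * mask, cache = mask)
}

relu_bw <- function(cache, gy) gy * cache

pool_fw <- function(x, pool = c(1, 4)) {       # pool = (ph, pw)
  r <- maxpool_fw(x, pool[1], pool[2])
  list(y = r$y, cache = list(idx = r$idx, xdim = dim(x)))
}

pool_bw <- function(cache, gy) maxpool_bw(cache$idx, gy, cache$xdim)

dropout_fw <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, cache = NULL))
  mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
  y <- x * mask
  dim(y) <- dim(x)
  list(y = y, cache = mask)
}

dropout_bw <- function(cache, gy) {
  if (is.null(cache)) return(gy)
  gy * cache
}

linear_fw <- function(p, x) {                  # x: (din, N)
  list(y = p$w %*% x + p$b, cache = x)
}

linear_bw <- function(p, cache, gy) {
  list(gx = crossprod(p$w, gy),
       grads = list(w = tcrossprod(gy, cache), b = rowSums(gy)))
}

# softmax cross-entropy; labels are 0-based class indices
softmax_xent <- function(logits, labels) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  ez <- exp(z)
  probs <- sweep(ez, 2, colSums(ez), "/")
  n <- ncol(logits)
  picked <- probs[cbind(labels + 1L, seq_len(n))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  grad <- probs
  grad[cbind(labels + 1L, seq_len(n))] <-
    grad[cbind(labels + 1L, seq_len(n))] - 1
  list(loss = loss, grad = grad / n, probs = probs)
}
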