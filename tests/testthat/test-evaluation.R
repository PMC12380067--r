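test_that("confusion matrices count, conserve and score correctly", {
  cl <- as.character(0:7)
  true <- rep(0:7, each = 10)
  cm <- confusion(true, true, cl)
  expect_equal(sum(diag(cm)), 80L)
  expect_equal(accuracy(cm), 1)
  # one error in 80 trials: the decoding-accuracy arithmetic anchor
  pred <- true; pred[1] <- 1
  cm2 <- confusion(true, pred, cl)
  expect_equal(accuracy(cm2), 0.9875)
  expect_equal(sum(cm2), 80L)                 # conservation
  expect_equal(unname(rowSums(cm2)), rep(10L, 8))
  # collapsing onto one class on balanced data gives chance accuracy
  cm3 <- confusion(true, rep(0L, 80), cl)
  expect_equal(accuracy(cm3), 0.125)
  # labels outside the class set are rejected unless registered
  expect_error(confusion(true, c(rep(0L, 79), 9L), cl), "outside")
  cm4 <- confusion(true, c(rep("0", 79), "XX"), cl, extra_pred_classes = "XX")
  expect_equal(ncol(cm4), 9L)
})

test_that("sweeps retrain per grid point and carry dispersion", {
  # singleton grid equals direct evaluation
  fake_data <- function(value, seed) list(value = value, seed = seed)
  fake_eval <- function(ds, seed) 0.5 + 0.01 * ds$value
  sw <- sweep_parameter(fake_data, fake_eval, "x", 3, n_seeds = 1)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$mean_acc, fake_eval(fake_data(3, 1), 1))
  expect_true(attr(sw, "single_seed"))
  sw3 <- sweep_parameter(fake_data, function(d, s) 0.5 + 0.01 * s, "x", c(1, 2),
                         n_seeds = 3)
  expect_false(attr(sw3, "single_seed"))
  expect_true(all(sw3$sd_acc > 0))
  # failures are recorded, not dropped
  flaky <- function(ds, seed) if (seed == 2) stop("boom") else 0.9
  swf <- sweep_parameter(fake_data, flaky, "x", 1, n_seeds = 3)
  expect_equal(swf$n_ok, 2L)
  expect_length(attr(swf, "failures"), 1L)
  expect_error(sweep_parameter(fake_data, fake_eval, "x", numeric(0)),
               "non-empty")
})

train_eval_tiny <- function(ds, seed) {
  model <- build_decoder(ds$cfg)
  fit <- train_decoder(model, ds$train, train_config(epochs = 10, seed = seed))
  mean(predict_decoder(fit, ds$test)$labels == attr(ds$test, "labels"))
}

test_that("more channels cannot hurt decoding on average", {
  factory <- function(n_ch, seed) {
    spec <- synth_spec(snr_db = 10, n_channels = n_ch, seed = 300L + seed)
    train <- to_tensor(lapply(synth_dataset(8, spec), preprocess_trial))
    spec$seed <- 400L + seed
    test <- to_tensor(lapply(synth_dataset(4, spec), preprocess_trial))
    cfg <- decoder_config(channels = n_ch, seed = seed)
    list(train = train, test = test, cfg = cfg)
  }
  sw <- sweep_parameter(factory, train_eval_tiny, "channels", c(1, 8),
                        n_seeds = 3)
  expect_gte(sw$mean_acc[sw$value == 8], sw$mean_acc[sw$value == 1])
})

test_that("longer trials cannot hurt decoding on average", {
  factory <- function(dur, seed) {
    spec <- synth_spec(snr_db = 10, duration = dur, seed = 500L + seed)
    train <- to_tensor(lapply(synth_dataset(8, spec), preprocess_trial))
    spec$seed <- 600L + seed
    test <- to_tensor(lapply(synth_dataset(4, spec), preprocess_trial))
    cfg <- decoder_config(time_steps = as.integer(1000 * dur),
                          time_pools = c(4, 4, 2), seed = seed)
    list(train = train, test = test, cfg = cfg)
  }
  sw <- sweep_parameter(factory, train_eval_tiny, "signal_length", c(0.5, 1),
                        n_seeds = 3)
  expect_gte(sw$mean_acc[sw$value == 1], sw$mean_acc[sw$value == 0.5])
})

test_that("t-SNE preserves gross cluster structure deterministically", {
  set.seed(6)
  blobs <- rbind(matrix(stats::rnorm(60 * 64), 60),
                 matrix(stats::rnorm(60 * 64, mean = 10), 60))
  y1 <- tsne_embed(blobs, seed = 3, perplexity = 15, n_iter = 300)
  y2 <- tsne_embed(blobs, seed = 3, perplexity = 15, n_iter = 300)
  expect_identical(y1, y2)
  sil <- cluster::silhouette(rep(1:2, each = 60), stats::dist(y1))
  expect_gt(mean(sil[, 3]), 0.8)
  # duplicated points land nearly on top of each other
  dup <- blobs[c(1, 1, 30, 30), ]
  yd <- tsne_embed(rbind(blobs, dup), seed = 3, perplexity = 15, n_iter = 300)
  d_dup <- sqrt(sum((yd[121, ] - yd[122, ])^2))
  spread <- mean(stats::dist(yd))
  expect_lt(d_dup, 0.05 * spread)
  # guardrails
  expect_error(tsne_embed(blobs[1, , drop = FALSE]), "2 points")
  expect_error(tsne_embed(blobs, perplexity = 50), "perplexity")
})
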