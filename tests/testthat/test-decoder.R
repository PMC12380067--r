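test_that("decoder forward pass honors the classifier contract", {
  cfg <- decoder_config(seed = 2)
  model <- build_decoder(cfg)
  set.seed(4)
  x <- array(rnorm(4 * 8 * 1000), dim = c(4, 1, 8, 1000))
  attr(x, "fs") <- 1000
  pr <- predict_decoder(model, x)
  expect_length(pr$labels, 4L)
  expect_true(all(pr$labels %in% 0:7))
  expect_equal(dim(pr$probs), c(4L, 8L))
  expect_equal(rowSums(pr$probs), rep(1, 4), tolerance = 1e-12)
  expect_equal(dim(pr$embeddings), c(4L, 2L * cfg$branch_dim))
  # single trial
  pr1 <- predict_decoder(model, x[1, , , , drop = FALSE])
  expect_length(pr1$labels, 1L)
  expect_equal(dim(pr1$embeddings), c(1L, 64L))
  # shape mismatch is an error
  bad <- array(0, dim = c(2, 1, 4, 1000))
  expect_error(predict_decoder(model, bad), "shape")
})

test_that("building is seeded and evaluation is deterministic", {
  m1 <- build_decoder(decoder_config(seed = 31))
  m2 <- build_decoder(decoder_config(seed = 31))
  expect_identical(m1$params, m2$params)
  m3 <- build_decoder(decoder_config(seed = 32))
  expect_false(identical(m1$params, m3$params))
  d <- small_decoder_data()
  p1 <- predict_decoder(m1, d$test)
  p2 <- predict_decoder(m1, d$test)
  expect_identical(p1, p2)
})

test_that("cosine annealing with warm restarts starts at lr0 and restarts", {
  cfg <- train_config(lr0 = 0.2, restart_period = 50, restart_mult = 2)
  expect_equal(cosine_lr(0, cfg), 0.2)
  expect_equal(cosine_lr(50, cfg), 0.2)     # first warm restart
  expect_equal(cosine_lr(150, cfg), 0.2)    # second (period doubled)
  expect_lt(cosine_lr(49, cfg), 0.001)      # annealed to near zero
  lrs <- cosine_lr(0:49, cfg)
  expect_true(all(diff(lrs) < 0))
})

test_that("augmentation selects a Bernoulli fraction and preserves labels", {
  cfg0 <- train_config(augment_fraction = 0, seed = 1)
  batch <- array(rnorm(64 * 10), dim = c(64, 1, 1, 10))
  expect_equal(as.numeric(augment(batch, cfg0)), as.numeric(batch))
  cfg1 <- train_config(augment_fraction = 1, augment_noise_scale = 0)
  expect_equal(as.numeric(augment(batch, cfg1)), as.numeric(batch))
  # concentration of the selected proportion at n = 10,000
  big <- array(0, dim = c(10000, 1, 1, 2))
  set.seed(12)
  sel <- attr(augment(big, train_config(augment_fraction = 0.5)), "augmented")
  expect_gte(mean(sel), 0.48)
  expect_lte(mean(sel), 0.52)
  # noise actually lands on selected samples only
  set.seed(3)
  out <- augment(batch, train_config(augment_fraction = 0.5,
                                     augment_noise_scale = 1))
  sel <- attr(out, "augmented")
  changed <- apply(out != batch, 1, any)
  expect_equal(changed, sel)
})

test_that("short training runs are seed-deterministic and learn", {
  d <- small_decoder_data()
  model <- build_decoder(decoder_config(seed = 5))
  tc <- train_config(epochs = 3, seed = 13)
  r1 <- train_decoder(model, d$train, tc)
  r2 <- train_decoder(model, d$train, tc)
  expect_equal(r1$history$loss, r2$history$loss, tolerance = 1e-12)
  expect_identical(r1$params, r2$params)
  # loss drops and the lr trace matches the schedule
  expect_lt(tail(r1$history$loss, 1), r1$history$loss[1])
  expect_equal(r1$history$lr, cosine_lr(0:2, tc))
  # empty/unlabelled data is an error
  expect_error(train_decoder(model, array(0, c(0, 1, 8, 1000))), "labelled")
})

test_that("a briefly trained decoder separates synthetic SSVEP classes", {
  d <- small_decoder_data()
  m <- small_trained_decoder()
  pr <- predict_decoder(m, d$test)
  acc <- mean(pr$labels == attr(d$test, "labels"))
  expect_gt(acc, 0.9)
  # class-feature quality: mean silhouette of the pre-classifier embedding
  sil <- cluster::silhouette(attr(d$test, "labels") + 1L,
                             stats::dist(pr$embeddings))
  expect_gt(mean(sil[, 3]), 0.5)
})

test_that("held-out accuracy degrades monotonically with SNR", {
  accs <- sapply(c(20, 0, -10), function(snr) {
    mean(sapply(1:3, function(s) {
      spec <- synth_spec(snr_db = snr, seed = 1000L + s)
      train <- to_tensor(lapply(synth_dataset(8, spec), preprocess_trial))
      spec$seed <- 2000L + s
      test <- to_tensor(lapply(synth_dataset(4, spec), preprocess_trial))
      model <- build_decoder(decoder_config(seed = s))
      fit <- train_decoder(model, train, train_config(epochs = 10, seed = s))
      mean(predict_decoder(fit, test)$labels == attr(test, "labels"))
    }))
  })
  expect_true(all(diff(accs) <= 0))
})
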