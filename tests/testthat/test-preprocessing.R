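tone_trial <- function(freq, fs = 1000, dur = 1, amp = 1) {
  t <- (seq_len(fs * dur) - 1) / fs
  eeg_trial(matrix(rep(amp * sin(2 * pi * freq * t), 8), 8, byrow = TRUE), fs)
}

rms <- function(x) sqrt(mean(x^2))

# squared magnitude response of the designed Butterworth at f (the filters
# run forward-backward, so attenuation is |H|^2), from the transfer function
designed_response <- function(band, type, f, fs = 1000, order = 2) {
  flt <- signal::butter(order, band / (fs / 2), type = type)
  w <- 2 * pi * f / fs
  num <- sum(flt$b * exp(-1i * w * (seq_along(flt$b) - 1)))
  den <- sum(flt$a * exp(-1i * w * (seq_along(flt$a) - 1)))
  Mod(num / den)^2
}

test_that("notch filters attenuate the power line and pass the SSVEP band", {
  spec <- filter_spec()
  # oracle: designed zero-phase response at 50 Hz is essentially zero,
  # at 10 Hz essentially unity
  expect_lt(designed_response(c(48, 52), "stop", 50), 1e-6)
  expect_gt(designed_response(c(48, 52), "stop", 10), 0.98)
  # steady-state attenuation measured over the central window (a tone that
  # switches on at t = 0 carries legitimate broadband onset energy that no
  # notch should remove)
  core <- 500:1500
  out50 <- notch_filter(tone_trial(50, dur = 2), spec)
  expect_lt(rms(out50$data[, core]) / rms(tone_trial(50, dur = 2)$data[, core]),
            0.05)
  out10 <- notch_filter(tone_trial(10), spec)
  expect_lt(abs(rms(out10$data) / rms(tone_trial(10)$data) - 1), 0.02)
  # 100 Hz harmonic band-stop is part of the default chain
  out100 <- notch_filter(tone_trial(100, dur = 2), spec)
  expect_lt(rms(out100$data[, core]) /
            rms(tone_trial(100, dur = 2)$data[, core]), 0.05)
  # zeros in, zeros out
  z <- eeg_trial(matrix(0, 8, 1000), 1000)
  expect_equal(notch_filter(z, spec)$data, matrix(0, 8, 1000))
})

test_that("band-pass removes DC, passes 10 Hz, rolls off 150 Hz", {
  spec <- filter_spec()
  dc <- eeg_trial(matrix(100, 8, 1000), 1000)
  expect_lt(max(abs(rowMeans(bandpass_filter(dc, spec)$data))), 1)
  out10 <- bandpass_filter(tone_trial(10), spec)
  expect_lt(abs(rms(out10$data) / rms(tone_trial(10)$data) - 1), 0.05)
  # 150 Hz attenuated at least as much as the designed rolloff predicts
  # (measured over the steady-state center to avoid edge transients)
  pred <- designed_response(c(4, 100), "pass", 150)
  out150 <- bandpass_filter(tone_trial(150, dur = 2), spec)
  center <- 500:1500
  expect_lt(rms(out150$data[, center]), sqrt(pred) * 1.1 / sqrt(2))
})

test_that("filtering is linear and preserves shape", {
  spec <- filter_spec()
  set.seed(31)
  x <- eeg_trial(matrix(rnorm(8 * 1000), 8), 1000)
  y <- eeg_trial(matrix(rnorm(8 * 1000), 8), 1000)
  combo <- eeg_trial(2 * x$data - 3 * y$data, 1000)
  lhs <- preprocess_trial(combo, spec)$data
  rhs <- 2 * preprocess_trial(x, spec)$data - 3 * preprocess_trial(y, spec)$data
  expect_lt(max(abs(lhs - rhs)), 1e-8)
  expect_equal(dim(lhs), c(8L, 1000L))
})

test_that("zero-phase contract: no lag on a passband tone", {
  spec <- filter_spec()
  tr <- tone_trial(10)
  out <- bandpass_filter(tr, spec)
  cc <- stats::ccf(out$data[1, ], tr$data[1, ], lag.max = 25, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # causal variant produces a different (phase-shifted) waveform
  out_c <- bandpass_filter(tr, filter_spec(causal = TRUE))
  expect_false(isTRUE(all.equal(out_c$data, out$data, tolerance = 1e-3)))
})

test_that("bands outside Nyquist are rejected", {
  tr <- tone_trial(10, fs = 150)
  expect_error(notch_filter(tr, filter_spec(notch_bands = list(c(98, 102)))),
               "fs/2")
  expect_error(bandpass_filter(tr, filter_spec(bandpass = c(4, 80))), "fs/2")
})

test_that("to_tensor stacks trials and keeps label order", {
  spec <- synth_spec(seed = 3, duration = 0.5)
  trials <- synth_dataset(2, spec)
  x <- to_tensor(trials)
  expect_equal(dim(x), c(16L, 1L, 8L, 500L))
  expect_equal(attr(x, "labels"), rep(0:7, each = 2))
  expect_equal(x[3, 1, , ], trials[[3]]$data)
  # single trial keeps a batch dimension
  x1 <- to_tensor(trials[1])
  expect_equal(dim(x1), c(1L, 1L, 8L, 500L))
  # a fixed permutation permutes labels identically
  set.seed(8)
  perm <- sample(16)
  xp <- to_tensor(trials[perm])
  expect_equal(attr(xp, "labels"), rep(0:7, each = 2)[perm])
  expect_equal(xp[1, 1, , ], trials[[perm[1]]]$data)
  # heterogeneous shapes rejected
  bad <- c(trials[1], list(eeg_trial(matrix(0, 8, 100), 1000)))
  expect_error(to_tensor(bad), "mismatch")
})
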