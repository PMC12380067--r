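#' Specification for the synthetic SSVEP generator
#'
#' Collects every knob of the labelled-trial generator. The generated trial is
#' a harmonic stack at the target frequency, mixed across channels by a fixed
#' all-positive gain vector, plus broadband noise scaled to a target
#' signal-to-noise ratio defined over the 4--100 Hz band.
#'
#' @param n_harmonics Number of harmonics of the target frequency (>= 1).
#' @param harmonic_decay Power-law exponent `p`: harmonic `k` has relative
#'   amplitude `k^-p`. The default `p = 1` gives the 1/k roll-off typical of a
#'   periodic non-sinusoidal response.
#' @param noise_model One of `"mixture"` (pink + white at equal band power,
#'   the default; EEG background is approximately 1/f), `"pink"`, `"white"`.
#' @param snr_db Signal-to-noise ratio in dB: SSVEP component power over noise
#'   power, both measured in the 4--100 Hz band. `Inf` disables noise.
#' @param duration Trial duration in seconds (>= 0.2).
#' @param fs Sampling rate in samples/s (default 1000).
#' @param amplitude Fundamental amplitude in microvolts before channel gains.
#' @param n_channels Number of channels (default 8, occipital montage).
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_harmonics = 3L, harmonic_decay = 1,
                       noise_model = c("mixture", "pink", "white"),
                       snr_db = 10, duration = 1, fs = 1000,
                       amplitude = 5, n_channels = 8L, seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (!is.finite(duration) || duration < 0.2) {
    stop("invalid synth_spec: duration must be >= 0.2 s", call. = FALSE)
  }
  stopifnot_scalar(fs, "fs")
  if (n_harmonics < 1) stop("n_harmonics must be >= 1", call. = FALSE)
  structure(list(
    n_harmonics = as.integer(n_harmonics), harmonic_decay = harmonic_decay,
    noise_model = noise_model, snr_db = snr_db, duration = duration,
    fs = fs, amplitude = amplitude, n_channels = as.integer(n_channels),
    seed = as.integer(seed)
  ), class = "synth_spec")
}

#' Construct an EEG trial object
#'
#' @param data Channels x samples numeric matrix, microvolts.
#' @param fs Sampling rate in samples/s.
#' @param channel_names Ordered channel names (defaults to the occipital
#'   montage for 8 channels).
#' @param label Target index 0--7, or `NA` for unlabelled data.
#' @return An object of class `eeg_trial`.
#' @export
eeg_trial <- function(data, fs, channel_names = NULL, label = NA_integer_) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("trial data must be finite", call. = FALSE)
  if (is.null(channel_names)) {
    channel_names <- if (nrow(data) == 8L) default_channels()
                     else paste0("ch", seq_len(nrow(data)))
  }
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 label = label), class = "eeg_trial")
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("<eeg_trial> %d ch x %d samples @ %g SPS, label = %s\n",
              nrow(x$data), ncol(x$data), x$fs,
              ifelse(is.na(x$label), "unlabelled", x$label)))
  invisible(x)
}

# 1/f-shaped noise via spectral shaping; unit variance overall.
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))          # guard DC
  f <- pmin(f, n - f + 1)            # symmetric in the mirrored half
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

noise_matrix <- function(model, n_channels, n) {
  gen <- function() switch(model,
    white = stats::rnorm(n),
    pink = pink_noise(n),
    mixture = {
      w <- stats::rnorm(n)
      p <- pink_noise(n)
      (w / stats::sd(w) + p) / sqrt(2)
    })
  t(vapply(seq_len(n_channels), function(i) gen(), numeric(n)))
}

# SSVEP waveform: sum over harmonics of k^-p-scaled sinusoids. The stimulus
# phase enters each harmonic as k * phase, consistent with a periodic
# non-sinusoidal response to a phase-shifted stimulus.
ssvep_waveform <- function(frequency, phase, spec) {
  n <- round(spec$fs * spec$duration)
  t <- (seq_len(n) - 1) / spec$fs
  k <- seq_len(spec$n_harmonics)
  amps <- spec$amplitude * k^(-spec$harmonic_decay)
  colSums(amps * sin(outer(2 * pi * k * frequency, t) + k * phase))
}

#' Synthesize one labelled SSVEP trial
#'
#' The clean component is a harmonic stack at the target's frequency/phase,
#' scaled per channel by an all-positive gain vector (every occipital channel
#' sees the SSVEP, at different amplitude). Independent broadband noise is
#' added per channel, scaled so that the realized SSVEP-to-noise power ratio
#' over 4--100 Hz equals `spec$snr_db`.
#'
#' @param target A target index (0--7) or a row of [target_table()].
#' @param spec A [synth_spec()].
#' @param channel_gains Optional positive gain vector (length `n_channels`);
#'   drawn from the seed when `NULL`.
#' @return An [eeg_trial()] with attribute `components` holding the separately
#'   stored signal and noise matrices (useful for SNR verification).
#' @export
synth_ssvep_trial <- function(target, spec, channel_gains = NULL) {
  if (!inherits(spec, "synth_spec")) stop("spec must be a synth_spec")
  if (is.numeric(target)) target <- target_code(target)
  n <- round(spec$fs * spec$duration)
  with_seed(spec$seed, {
    if (is.null(channel_gains)) {
      channel_gains <- stats::runif(spec$n_channels, 0.5, 1.5)
    }
    wave <- ssvep_waveform(target$frequency, target$phase, spec)
    signal <- outer(channel_gains, wave)
    if (is.finite(spec$snr_db)) {
      noise <- noise_matrix(spec$noise_model, spec$n_channels, n)
      p_sig <- band_power(signal, spec$fs)
      p_noise <- band_power(noise, spec$fs)
      scale <- sqrt(p_sig / (p_noise * 10^(spec$snr_db / 10)))
      noise <- noise * scale
    } else {
      noise <- matrix(0, spec$n_channels, n)
    }
    out <- eeg_trial(signal + noise, spec$fs, label = target$index)
    attr(out, "components") <- list(signal = signal, noise = noise)
    out
  })
}

#' Synthesize a balanced labelled dataset
#'
#' Generates `8 * n_per_class` trials, `n_per_class` per target, with
#' per-trial seeds derived deterministically from `spec$seed` and one channel
#' gain vector shared by the whole run.
#'
#' @param n_per_class Trials per target (>= 1).
#' @param spec A [synth_spec()]; `spec$seed` is the master seed.
#' @return List of [eeg_trial()] objects in target-major order.
#' @export
synth_dataset <- function(n_per_class, spec) {
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  gains <- with_seed(spec$seed, stats::runif(spec$n_channels, 0.5, 1.5))
  labels <- rep(0:7, each = n_per_class)
  seeds <- derive_seeds(spec$seed, length(labels))
  lapply(seq_along(labels), function(i) {
    spec_i <- spec
    spec_i$seed <- seeds[i]
    synth_ssvep_trial(labels[i], spec_i, channel_gains = gains)
  })
}
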