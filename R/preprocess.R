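#' Filtering specification for raw EEG
#'
#' Defaults mirror the acquisition pipeline: two second-order Butterworth
#' band-stops around the 50 Hz power line and its 100 Hz harmonic, and a
#' second-order Butterworth band-pass at 4--100 Hz. All filters are applied
#' forward-backward (zero phase) by default, since decoding uses waveform
#' shape; set `causal = TRUE` for single-pass causal filtering.
#'
#' @param notch_bands List of `(low, high)` Hz band-stop edges.
#' @param bandpass `(low, high)` Hz band-pass edges.
#' @param order Butterworth order per filter (default 2).
#' @param causal Logical; `FALSE` (default) applies each filter forward and
#'   backward.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(notch_bands = list(c(48, 52), c(98, 102)),
                        bandpass = c(4, 100), order = 2L, causal = FALSE) {
  structure(list(notch_bands = notch_bands, bandpass = bandpass,
                 order = as.integer(order), causal = causal),
            class = "filter_spec")
}

check_band <- function(band, fs) {
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2] ||
      band[2] >= fs / 2) {
    stop(sprintf("invalid filter band (%s) for fs = %g: need 0 < low < high < fs/2",
                 paste(band, collapse = ", "), fs), call. = FALSE)
  }
}

# Forward-backward IIR filtering with odd-reflection edge padding, applied
# per channel. Narrow-band (notch) filters ring for far longer than the
# classic 3 * (n_coef - 1) heuristic, so pad generously relative to the
# signal length.
zero_phase_filter <- function(x, b, a) {
  n <- length(x)
  np <- min(n - 1L, max(250L, 3L * (max(length(a), length(b)) - 1L)))
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  y <- as.numeric(signal::filter(b, a, xp))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(np + 1):(np + n)]
}

apply_iir <- function(trial, b, a, causal) {
  data <- trial$data
  out <- t(apply(data, 1L, function(ch) {
    if (causal) as.numeric(signal::filter(b, a, ch))
    else zero_phase_filter(ch, b, a)
  }))
  trial$data <- out
  trial
}

#' Band-stop (notch) filtering of one trial
#'
#' Attenuates the configured power-line bands with Butterworth band-stop
#' filters, zero-phase by default.
#'
#' @param trial An [eeg_trial()].
#' @param spec A [filter_spec()].
#' @return The filtered [eeg_trial()] (same shape).
#' @export
notch_filter <- function(trial, spec = filter_spec()) {
  for (band in spec$notch_bands) {
    check_band(band, trial$fs)
    flt <- signal::butter(spec$order, band / (trial$fs / 2), type = "stop")
    trial <- apply_iir(trial, flt$b, flt$a, spec$causal)
  }
  trial
}

#' Band-pass filtering of one trial
#'
#' @inheritParams notch_filter
#' @return The filtered [eeg_trial()] (same shape).
#' @export
bandpass_filter <- function(trial, spec = filter_spec()) {
  check_band(spec$bandpass, trial$fs)
  flt <- signal::butter(spec$order, spec$bandpass / (trial$fs / 2),
                        type = "pass")
  apply_iir(trial, flt$b, flt$a, spec$causal)
}

#' Full preprocessing chain (notch then band-pass)
#'
#' @inheritParams notch_filter
#' @return The filtered [eeg_trial()].
#' @export
preprocess_trial <- function(trial, spec = filter_spec()) {
  bandpass_filter(notch_filter(trial, spec), spec)
}

#' Stack trials into a 4-D decoder input tensor
#'
#' @param trials List of [eeg_trial()] objects sharing sampling rate, channel
#'   count and length.
#' @return An array of shape `(batch, 1, channels, time_steps)` with
#'   attributes `labels` (integer vector, `NA` where unlabelled) and `fs`.
#' @export
to_tensor <- function(trials) {
  if (length(trials) == 0L) stop("no trials supplied", call. = FALSE)
  dims <- vapply(trials, function(tr) dim(tr$data), integer(2))
  fss <- vapply(trials, function(tr) tr$fs, numeric(1))
  if (length(unique(dims[1, ])) > 1L || length(unique(dims[2, ])) > 1L ||
      length(unique(fss)) > 1L) {
    stop("shape mismatch: trials must share fs, channel count and length",
         call. = FALSE)
  }
  n <- length(trials); ch <- dims[1, 1]; tt <- dims[2, 1]
  x <- array(0, dim = c(n, 1, ch, tt))
  for (i in seq_len(n)) x[i, 1, , ] <- trials[[i]]$data
  attr(x, "labels") <- vapply(trials, function(tr) as.integer(tr$label),
                              integer(1))
  attr(x, "fs") <- fss[1]
  x
}
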