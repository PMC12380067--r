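#' Short-time Fourier transform of a trial tensor
#'
#' Computes a magnitude spectrogram per channel with a Hann window, the
#' frequency-domain input of the decoder's second branch. Frames are
#' non-centered: frame `j` covers samples `[(j-1)*hop + 1, (j-1)*hop + window]`,
#' so the frame count is `floor((time_steps - window)/hop) + 1`.
#'
#' @param tensor Array `(batch, 1, channels, time_steps)` from [to_tensor()],
#'   or a single trial's channels x samples matrix.
#' @param config A [decoder_config()] (uses `stft_window`, `stft_hop`,
#'   `freq_max_hz`) -- individual values may also be passed.
#' @param fs Sampling rate; taken from the tensor's `fs` attribute if present.
#' @return Array `(batch, channels, height, width)` of non-negative
#'   magnitudes, `height` = retained frequency bins (up to `freq_max_hz`),
#'   `width` = frames; attributes `freqs` (Hz) and `times` (frame centers, s).
#' @export
stft_transform <- function(tensor, config = decoder_config(), fs = NULL) {
  if (is.matrix(tensor)) {
    tmp <- array(0, dim = c(1, 1, nrow(tensor), ncol(tensor)))
    tmp[1, 1, , ] <- tensor
    attr(tmp, "fs") <- fs
    tensor <- tmp
  }
  if (is.null(fs)) fs <- attr(tensor, "fs")
  if (is.null(fs)) fs <- config$fs
  win <- config$stft_window
  hop <- config$stft_hop
  d <- dim(tensor)
  n_batch <- d[1]; n_ch <- d[3]; n_t <- d[4]
  if (win > n_t) stop("invalid config: STFT window longer than the signal",
                      call. = FALSE)
  if (hop >= win) stop("invalid config: hop must be smaller than the window",
                       call. = FALSE)
  core <- stft_core(tensor, config, fs)
  out <- aperm(core, c(4, 3, 2, 1))             # -> (batch, ch, bins, frames)
  attr(out, "freqs") <- attr(core, "freqs")
  attr(out, "times") <- attr(core, "times")
  out
}

# internal fast path: returns the decoder layout (frames, bins, channels,
# batch) with one batched FFT over every (frame, channel, trial) segment
stft_core <- function(tensor, config, fs = NULL) {
  if (is.null(fs)) fs <- attr(tensor, "fs")
  if (is.null(fs)) fs <- config$fs
  win <- config$stft_window
  hop <- config$stft_hop
  d <- dim(tensor)
  n_batch <- d[1]; n_ch <- d[3]; n_t <- d[4]
  if (win > n_t) stop("invalid config: STFT window longer than the signal",
                      call. = FALSE)
  if (hop >= win) stop("invalid config: hop must be smaller than the window",
                       call. = FALSE)
  n_frames <- floor((n_t - win) / hop) + 1
  freqs <- (0:(win %/% 2)) * fs / win
  keep <- which(freqs <= config$freq_max_hz)
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  starts <- (seq_len(n_frames) - 1) * hop
  seg_idx <- outer(1:win, starts, "+")          # win x frames sample indices
  tm <- aperm(tensor, c(4, 3, 1, 2))            # (T, C, N, 1)
  all_idx <- rep(as.vector(seg_idx), times = n_ch * n_batch) +
    rep((seq_len(n_ch * n_batch) - 1) * n_t, each = win * n_frames)
  segs <- matrix(tm[all_idx], nrow = win) * hann
  mag <- Mod(stats::mvfft(segs))[keep, , drop = FALSE]
  core <- array(mag, dim = c(length(keep), n_frames, n_ch, n_batch))
  core <- aperm(core, c(2, 1, 3, 4))            # (frames, bins, ch, batch)
  attr(core, "freqs") <- freqs[keep]
  attr(core, "times") <- (starts + win / 2) / fs
  core
}
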