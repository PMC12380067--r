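#' Peak-to-peak amplitude of a spike waveform
#'
#' @param waveform Numeric vector of samples (microvolts).
#' @return `max - min` in microvolts.
#' @export
p2p_amplitude <- function(waveform) {
  if (length(waveform) == 0L) stop("empty waveform", call. = FALSE)
  max(waveform) - min(waveform)
}

#' Signal-to-noise ratio of a spike waveform
#'
#' SNR conventions vary; here it is peak-to-peak amplitude over `k` times the
#' standard deviation of a spike-free noise trace, with `k` reported alongside
#' so numbers stay interpretable.
#'
#' @param waveform Spike waveform (microvolts).
#' @param noise_trace Spike-free noise samples; should cover >= 100 ms.
#' @param k Multiplier on the noise SD (default 2).
#' @return Unitless SNR with attribute `k`.
#' @export
spike_snr <- function(waveform, noise_trace, k = 2) {
  s <- stats::sd(noise_trace)
  if (!is.finite(s) || s == 0) stop("noise trace has zero variance", call. = FALSE)
  structure(p2p_amplitude(waveform) / (k * s), k = k)
}

#' Binned firing rate of a spike train
#'
#' @param spike_times Sorted spike times in seconds.
#' @param bin_s Bin width in seconds (> 0).
#' @param t_range Optional `(start, end)`; defaults to `(0, max(spike_times))`
#'   rounded up to a whole bin.
#' @return Data frame with `t` (bin centers, s) and `rate` (Hz); total counts
#'   integrate back to the number of spikes inside `t_range`.
#' @export
firing_rate <- function(spike_times, bin_s, t_range = NULL) {
  stopifnot_scalar(bin_s, "bin_s")
  if (is.unsorted(spike_times)) stop("spike times must be sorted", call. = FALSE)
  if (is.null(t_range)) {
    t_end <- if (length(spike_times)) ceiling(max(spike_times) / bin_s) * bin_s
             else bin_s
    t_range <- c(0, t_end)
  }
  breaks <- seq(t_range[1], t_range[2], by = bin_s)
  if (length(breaks) < 2L) breaks <- c(t_range[1], t_range[1] + bin_s)
  counts <- graphics::hist(spike_times[spike_times >= t_range[1] &
                                       spike_times <= t_range[2]],
                           breaks = breaks, plot = FALSE,
                           right = FALSE)$counts
  data.frame(t = utils::head(breaks, -1) + bin_s / 2, rate = counts / bin_s)
}

#' Correlation between firing rate and locomotion velocity
#'
#' Velocity is max-normalized to `[0, 1]` before the Pearson correlation, the
#' convention used when plotting normalized velocity against simultaneous
#' firings.
#'
#' @param rate_series Numeric firing-rate vector (Hz).
#' @param velocity_series Equal-length velocity vector (any positive unit).
#' @return Pearson correlation coefficient.
#' @export
rate_velocity_correlation <- function(rate_series, velocity_series) {
  if (length(rate_series) != length(velocity_series)) {
    stop("series must have equal length", call. = FALSE)
  }
  if (length(rate_series) < 10L) stop("need >= 10 bins", call. = FALSE)
  v <- velocity_series / max(velocity_series)
  if (stats::sd(rate_series) == 0 || stats::sd(v) == 0) {
    stop("undefined correlation: constant series", call. = FALSE)
  }
  stats::cor(rate_series, v)
}

#' Read a sorted spike table
#'
#' Import shim for externally spike-sorted output: CSV with columns
#' `time`, `neuron`, `channel`.
#' @param path CSV path.
#' @return Data frame sorted by time.
#' @export
read_spike_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time", "neuron", "channel") %in% names(df))) {
    stop("spike CSV must have columns time, neuron, channel", call. = FALSE)
  }
  df[order(df$time), ]
}
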