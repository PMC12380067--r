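#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of per-item seeds from a master seed; kept < 2^31 - 1.
derive_seeds <- function(master, n) {
  (as.double(master) * 48271 + 7919 * seq_len(n)) %% 2147483629
}

#' Band-limited signal power
#'
#' Mean power (per-sample variance contribution) of `x` restricted to a
#' frequency band, computed from the discrete Fourier transform with a
#' rectangular window.
#'
#' @param x Numeric vector (one channel) or matrix (channels x samples).
#' @param fs Sampling rate in samples/s.
#' @param band Length-2 numeric `(low, high)` in Hz.
#' @return Scalar power; for a matrix, summed over channels.
#' @export
band_power <- function(x, fs, band = c(4, 100)) {
  if (is.matrix(x)) return(sum(apply(x, 1L, band_power, fs = fs, band = band)))
  n <- length(x)
  spec <- abs(stats::fft(x))^2 / n^2
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  sel <- half & freqs >= band[1] & freqs <= band[2]
  # double one-sided bins except DC/Nyquist (neither lies inside 4-100 Hz here)
  2 * sum(spec[sel])
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) ||
      (positive && x <= 0)) {
    stop(sprintf("'%s' must be a single finite%s number", name,
                 if (positive) " positive" else ""), call. = FALSE)
  }
  invisible(x)
}
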