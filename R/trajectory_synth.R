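#' Specification for command-conditioned synthetic trajectories
#'
#' Emulates the video-tracked movement of one mouse across the three
#' experiment phases: near-stationary before stimulation, command-dependent
#' motion during stimulation, near-stationary after. The command letter sets
#' the sign of the heading drift during stimulation: `L` turns
#' counterclockwise (positive angular displacement), `R` clockwise (negative),
#' `X` receives no stimulation and stays at baseline.
#'
#' @param command_letter One of `"L"`, `"R"`, `"X"`.
#' @param phase_durations Numeric length-3 `(before, during, after)` in
#'   seconds; all > 0. Default 10 s each, matching a 10-s stimulation bout.
#' @param turn_rate Heading drift during stimulation, deg/s (positive;
#'   the sign comes from the command letter).
#' @param speed Locomotion speed during stimulation, mm/s.
#' @param jitter Unitless noise scale: 0 gives perfectly clean motion;
#'   1 (default) gives moderate tracking/behavioral noise.
#' @param fs Sampling rate of the track, samples/s (default 30,
#'   video-tracking-like).
#' @param seed Integer seed; fully determines the trajectory.
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(command_letter = c("L", "R", "X"),
                            phase_durations = c(10, 10, 10),
                            turn_rate = 25, speed = 40, jitter = 1,
                            fs = 30, seed = 1L) {
  command_letter <- match.arg(command_letter)
  if (length(phase_durations) != 3L || any(!is.finite(phase_durations)) ||
      any(phase_durations <= 0)) {
    stop("phase_durations must be three positive durations", call. = FALSE)
  }
  structure(list(command_letter = command_letter,
                 phase_durations = phase_durations, turn_rate = turn_rate,
                 speed = speed, jitter = jitter, fs = fs,
                 seed = as.integer(seed)), class = "trajectory_spec")
}

#' Phase windows of a stimulation bout
#'
#' @param before,during,after Length-2 `(start, end)` windows in seconds;
#'   must be ordered and non-overlapping.
#' @return An object of class `phase_windows`.
#' @export
phase_windows <- function(before, during, after) {
  w <- list(before = before, during = during, after = after)
  for (p in w) {
    if (length(p) != 2L || p[1] >= p[2]) {
      stop("each phase window must be (start, end) with start < end",
           call. = FALSE)
    }
  }
  if (before[2] > during[1] || during[2] > after[1]) {
    stop("phase windows must be ordered and non-overlapping", call. = FALSE)
  }
  structure(w, class = "phase_windows")
}

#' Synthesize one command-conditioned trajectory
#'
#' Positions are sampled at `spec$fs`. During stimulation (for `L`/`R`) the
#' animal moves at `spec$speed` while its heading drifts at
#' `+/- spec$turn_rate`; heading noise and a slow sub-threshold positional
#' wander scale with `spec$jitter`. Outside stimulation (and throughout for
#' `X`) the track is a near-stationary random walk whose steps stay below the
#' behavior module's minimum-motion epsilon, so baseline angular displacement
#' is near zero.
#'
#' @param spec A [trajectory_spec()].
#' @return A data frame with columns `t` (s), `x`, `y` (mm), carrying
#'   attributes `phases` (a [phase_windows()]) and `command_letter`.
#' @export
synth_trajectory <- function(spec) {
  if (!inherits(spec, "trajectory_spec")) stop("spec must be a trajectory_spec")
  dt <- 1 / spec$fs
  n_phase <- round(spec$phase_durations * spec$fs)
  n <- sum(n_phase)
  bounds <- cumsum(c(0, spec$phase_durations))
  stim_sign <- switch(spec$command_letter, L = 1, R = -1, X = 0)
  with_seed(spec$seed, {
    phase_id <- rep(1:3, n_phase)
    stimulated <- phase_id == 2L & stim_sign != 0
    # heading increments (radians per step)
    dtheta <- ifelse(stimulated, stim_sign * spec$turn_rate * pi / 180 * dt, 0)
    dtheta <- dtheta + ifelse(stimulated,
                              stats::rnorm(n, 0, spec$jitter * 3 * pi / 180),
                              stats::rnorm(n, 0, spec$jitter * 20 * pi / 180))
    heading <- cumsum(dtheta)
    # step lengths: locomotion when stimulated, sub-epsilon wander otherwise
    step <- ifelse(stimulated, spec$speed * dt,
                   spec$jitter * 0.02 * abs(stats::rnorm(n)))
    # displacement direction at the step midpoint so velocity-derived heading
    # matches the generating heading series
    mid <- heading - dtheta / 2
    x <- cumsum(step * cos(mid))
    y <- cumsum(step * sin(mid))
    out <- data.frame(t = seq_len(n) * dt, x = x, y = y)
    attr(out, "phases") <- phase_windows(
      before = c(bounds[1], bounds[2]),
      during = c(bounds[2], bounds[3]),
      after = c(bounds[3], bounds[4]))
    attr(out, "command_letter") <- spec$command_letter
    out
  })
}
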