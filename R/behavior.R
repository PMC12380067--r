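#' Heading series of a trajectory
#'
#' Heading is taken from the velocity direction `atan2(dy, dx)` and unwrapped
#' so that no consecutive difference exceeds 180 degrees. Steps shorter than
#' `min_step` (tracked position is the only observable, and heading is
#' undefined when stationary) hold the previous heading; an initial
#' stationary stretch holds 0.
#'
#' @param traj Data frame with columns `t`, `x`, `y` (seconds, mm, mm),
#'   `t` strictly increasing.
#' @param min_step Minimum per-step displacement (mm) for a heading update.
#' @return Numeric vector of unwrapped headings in degrees, one per sample
#'   (the first sample repeats the first defined heading).
#' @export
heading_series <- function(traj, min_step = 1) {
  if (nrow(traj) < 2L) stop("need at least 2 trajectory points", call. = FALSE)
  if (any(diff(traj$t) <= 0)) stop("t must be strictly increasing", call. = FALSE)
  dx <- diff(traj$x); dy <- diff(traj$y)
  moving <- sqrt(dx^2 + dy^2) >= min_step
  raw <- atan2(dy, dx)
  # unwrap over moving steps only, holding the last heading in between
  h <- numeric(length(dx))
  last <- NA_real_
  first_def <- NA_real_
  for (i in seq_along(dx)) {
    if (moving[i]) {
      if (is.na(last)) {
        last <- raw[i]
        first_def <- raw[i]
      } else {
        d <- (raw[i] - last + pi) %% (2 * pi) - pi
        if (d == -pi) d <- pi
        last <- last + d
      }
    }
    h[i] <- if (is.na(last)) NA_real_ else last
  }
  # heading is unobservable until the first movement: adopt the first
  # observed heading retroactively so the initial stretch contributes no
  # spurious turn (all-stationary tracks get heading 0 throughout)
  h[is.na(h)] <- if (is.na(first_def)) 0 else first_def
  c(h[1], h) * 180 / pi
}

window_index <- function(traj, window) {
  sel <- traj$t >= window[1] & traj$t <= window[2]
  if (!any(sel)) stop("window contains no trajectory samples", call. = FALSE)
  which(sel)
}

#' Signed angular displacement over a time window
#'
#' Cumulative heading change over the window; counterclockwise (leftward)
#' turning is positive, clockwise (rightward) negative.
#'
#' @inheritParams heading_series
#' @param window Length-2 `(start, end)` in seconds.
#' @return Net heading change in degrees.
#' @export
angular_displacement <- function(traj, window, min_step = 1) {
  h <- heading_series(traj, min_step)
  idx <- window_index(traj, window)
  h[max(idx)] - h[min(idx)]
}

#' Linear displacement (path length) over a time window
#'
#' Sum of consecutive step lengths -- accumulated path, not net displacement,
#' which better reflects how much motion a stimulation evokes.
#'
#' @inheritParams angular_displacement
#' @return Path length in mm.
#' @export
linear_displacement <- function(traj, window) {
  idx <- window_index(traj, window)
  if (length(idx) < 2L) return(0)
  sum(sqrt(diff(traj$x[idx])^2 + diff(traj$y[idx])^2))
}

#' Maximum angular-displacement change per phase
#'
#' Within each phase the cumulative heading change from the phase start is
#' tracked and the signed value of largest magnitude is returned (the peak
#' excursion, not the endpoint; set `endpoint = TRUE` for the endpoint
#' variant).
#'
#' @inheritParams angular_displacement
#' @param phases A [phase_windows()].
#' @param endpoint Use the end-of-phase value instead of the peak excursion.
#' @return Named numeric `(before, during, after)` in degrees.
#' @export
max_angular_change <- function(traj, phases, min_step = 1, endpoint = FALSE) {
  h <- heading_series(traj, min_step)
  one <- function(window) {
    idx <- window_index(traj, window)
    cum <- h[idx] - h[idx[1]]
    if (endpoint) cum[length(cum)] else cum[which.max(abs(cum))]
  }
  c(before = one(phases$before), during = one(phases$during),
    after = one(phases$after))
}

#' Classify a turning angle into L / R / X
#'
#' A valid turn requires the absolute turning angle to exceed 20 degrees
#' (strictly); positive angles are leftward (`L`), negative rightward (`R`),
#' anything within the threshold is `X`.
#'
#' @param angle_deg Finite turning angle(s) in degrees.
#' @param threshold_deg Validity threshold (default 20).
#' @return Character vector over `{"L", "R", "X"}`.
#' @export
classify_turn <- function(angle_deg, threshold_deg = 20) {
  if (any(!is.finite(angle_deg))) stop("angle must be finite", call. = FALSE)
  ifelse(angle_deg > threshold_deg, "L",
         ifelse(angle_deg < -threshold_deg, "R", "X"))
}

#' Behavior-vs-command confusion matrix
#'
#' Rows are the 8 true commands; columns add the observed-only pattern `XX`:
#' neither mouse produced a valid turn, an outcome no preset command
#' prescribes (every command stimulates at least one mouse).
#'
#' @param true_commands Character vector over the 8 commands.
#' @param observed_pair_labels Character vector over the 8 commands plus
#'   `"XX"`.
#' @return A [confusion()] matrix (8 x 9) with attached accuracy.
#' @export
behavior_confusion <- function(true_commands, observed_pair_labels) {
  confusion(true_commands, observed_pair_labels,
            class_names = target_table()$command,
            extra_pred_classes = "XX")
}

#' Two-tailed unpaired t-test with significance stars
#'
#' Classic pooled-variance Student's t-test by default (`welch = TRUE` for
#' the unequal-variance variant). Stars follow the usual thresholds:
#' `ns` p > 0.05, `*` p <= 0.05, `**` p <= 0.01, `***` p <= 0.001,
#' `****` p <= 0.0001.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param welch Use the Welch correction (default `FALSE`).
#' @return List with `t_statistic`, `p_value`, `stars`, and `degenerate`
#'   (`TRUE` when both groups have zero variance and equal means, where
#'   p = 1 by convention).
#' @export
compare_phases <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  degenerate <- stats::sd(group_a) == 0 && stats::sd(group_b) == 0
  if (degenerate && mean(group_a) == mean(group_b)) {
    res <- list(statistic = 0, p.value = 1)
  } else if (degenerate) {
    res <- list(statistic = sign(mean(group_a) - mean(group_b)) * Inf,
                p.value = 0)
  } else {
    tt <- stats::t.test(group_a, group_b, var.equal = !welch,
                        alternative = "two.sided")
    res <- list(statistic = unname(tt$statistic), p.value = tt$p.value)
  }
  stars <- if (res$p.value > 0.05) "ns"
           else if (res$p.value > 0.01) "*"
           else if (res$p.value > 0.001) "**"
           else if (res$p.value > 0.0001) "***"
           else "****"
  list(t_statistic = res$statistic, p_value = res$p.value, stars = stars,
       degenerate = degenerate)
}

#' Read / write trajectory CSV
#'
#' Plain `t,x,y` CSV in seconds and mm.
#' @param traj Data frame with `t`, `x`, `y`.
#' @param path File path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(traj[, c("t", "x", "y")], path, row.names = FALSE)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  traj <- utils::read.csv(path)
  if (!all(c("t", "x", "y") %in% names(traj))) {
    stop("trajectory CSV must have columns t, x, y", call. = FALSE)
  }
  traj
}
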