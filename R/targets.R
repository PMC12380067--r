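#' The eight-target joint frequency-phase code
#'
#' The interface distinguishes eight visual targets by flicker frequency
#' (8--15 Hz in 1 Hz steps) jointly with a phase offset cycling through
#' 0, pi/2, pi, 3*pi/2. Each target maps to a two-letter command, one letter
#' per mouse: `L` = left turn (stimulate right M2), `R` = right turn
#' (stimulate left M2), `X` = no stimulation.
#'
#' @return A data frame with one row per target and columns `index` (0--7),
#'   `frequency` (Hz), `phase` (radians) and `command` (two-letter string).
#' @examples
#' target_table()
#' @export
target_table <- function() {
  index <- 0:7
  data.frame(
    index = index,
    frequency = 8 + index,
    phase = (index %% 4) * pi / 2,
    command = c("LL", "RR", "LR", "RL", "LX", "RX", "XL", "XR"),
    stringsAsFactors = FALSE
  )
}

#' Look up a single target definition
#'
#' @param index Target index in 0--7.
#' @return A one-row data frame (see [target_table()]).
#' @export
target_code <- function(index) {
  if (length(index) != 1L || !is.finite(index) || index %% 1 != 0 ||
      index < 0 || index > 7) {
    stop("target index must be a single integer in 0-7", call. = FALSE)
  }
  target_table()[index + 1L, , drop = FALSE]
}

#' Default occipital channel montage
#'
#' Ordered 8-channel occipital montage used for SSVEP acquisition.
#' @return Character vector of channel names.
#' @export
default_channels <- function() {
  c("O1", "POz", "PO3", "PO5", "Oz", "PO6", "PO4", "O2")
}
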