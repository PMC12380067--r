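#' Map a decoded class to the two-mouse stimulation command
#'
#' Each command is two letters, one per mouse: `L` = left turn, delivered by
#' stimulating the right M2; `R` = right turn via the left M2; `X` = no
#' stimulation.
#'
#' @param index Decoded class index 0--7.
#' @return List with `command` (two-letter string) and `mouse1`/`mouse2`
#'   actions, each one of `"stimulate-right-M2"`, `"stimulate-left-M2"`,
#'   `"none"`.
#' @export
class_to_command <- function(index) {
  cmd <- target_code(index)$command
  act <- function(letter) switch(letter,
    L = "stimulate-right-M2", R = "stimulate-left-M2", X = "none")
  letters2 <- strsplit(cmd, "")[[1]]
  list(command = cmd, mouse1 = act(letters2[1]), mouse2 = act(letters2[2]))
}

#' Biphasic stimulation-train parameters
#'
#' The default waveform is the deployed charge-balanced pulse: a leading
#' 200 us cathodic phase, a 100 us interphase gap, and a 400 us anodic phase
#' at half the cathodic amplitude, repeated at 100 Hz. Charge balance holds by
#' construction: `200 us x I = 400 us x I/2`.
#'
#' @param cathodic_amp_uA Cathodic current amplitude in uA (positive number;
#'   the cathodic phase is emitted as negative current).
#' @param cathodic_width_us,interphase_gap_us,anodic_width_us Phase widths
#'   in us.
#' @param anodic_amp_uA Anodic amplitude in uA; default half the cathodic.
#' @param rate_hz Pulse repetition rate (default 100 Hz).
#' @param duration_s Train duration in seconds (default 1).
#' @param fs_out Output sampling rate in Hz; must resolve every phase width
#'   exactly (default 1 MHz so all widths are integer sample counts).
#' @return An object of class `stim_params`.
#' @export
stim_params <- function(cathodic_amp_uA = 5, cathodic_width_us = 200,
                        interphase_gap_us = 100, anodic_width_us = 400,
                        anodic_amp_uA = cathodic_amp_uA / 2,
                        rate_hz = 100, duration_s = 1, fs_out = 1e6) {
  stopifnot_scalar(cathodic_amp_uA, "cathodic_amp_uA")
  stopifnot_scalar(fs_out, "fs_out")
  if (fs_out < 1e5) {
    stop("fs_out must be >= 100 kHz to resolve 100 us phase widths",
         call. = FALSE)
  }
  widths <- c(cathodic_width_us, interphase_gap_us, anodic_width_us)
  samp_us <- 1e6 / fs_out
  if (any(abs(widths / samp_us - round(widths / samp_us)) > 1e-9)) {
    stop(sprintf(paste0("fs_out = %g cannot represent the phase widths ",
                        "exactly; use a rate whose sample period divides ",
                        "%s us (e.g. 1e6)"),
                 fs_out, paste(widths, collapse = "/")), call. = FALSE)
  }
  period_us <- 1e6 / rate_hz
  if (sum(widths) > period_us) {
    stop("active pulse span exceeds the pulse period", call. = FALSE)
  }
  structure(list(cathodic_amp_uA = cathodic_amp_uA,
                 cathodic_width_us = cathodic_width_us,
                 interphase_gap_us = interphase_gap_us,
                 anodic_width_us = anodic_width_us,
                 anodic_amp_uA = anodic_amp_uA, rate_hz = rate_hz,
                 duration_s = duration_s, fs_out = fs_out),
            class = "stim_params")
}

#' Synthesize a charge-balanced biphasic stimulation train
#'
#' @param params A [stim_params()].
#' @return A `stim_train`: list with `i_uA` (signed current samples; cathodic
#'   negative), `t_s` (sample times), `fs_out`, `n_pulses` and the parameter
#'   snapshot.
#' @export
make_biphasic_train <- function(params = stim_params()) {
  fs <- params$fs_out
  n_total <- round(params$duration_s * fs)
  n_pulses <- round(params$duration_s * params$rate_hz)
  period <- round(fs / params$rate_hz)
  n_cat <- round(params$cathodic_width_us * 1e-6 * fs)
  n_gap <- round(params$interphase_gap_us * 1e-6 * fs)
  n_an <- round(params$anodic_width_us * 1e-6 * fs)
  pulse <- c(rep(-params$cathodic_amp_uA, n_cat), rep(0, n_gap),
             rep(params$anodic_amp_uA, n_an),
             rep(0, period - n_cat - n_gap - n_an))
  i <- rep(pulse, length.out = n_total)
  structure(list(i_uA = i, t_s = (seq_len(n_total) - 1) / fs, fs_out = fs,
                 n_pulses = n_pulses, params = params),
            class = "stim_train")
}

#' @export
print.stim_train <- function(x, ...) {
  cat(sprintf("<stim_train> %d pulses @ %g Hz, %g/%g uA, net charge %.3g nC\n",
              x$n_pulses, x$params$rate_hz, -x$params$cathodic_amp_uA,
              x$params$anodic_amp_uA, sum(x$i_uA) / x$fs_out * 1e3))
  invisible(x)
}

#' Per-pulse charges of a stimulation train
#'
#' @param train A [make_biphasic_train()] result.
#' @return Data frame with per-pulse cathodic, anodic and net charge in nC.
#' @export
pulse_charges <- function(train) {
  period <- round(train$fs_out / train$params$rate_hz)
  idx <- rep(seq_len(train$n_pulses), each = period)[seq_along(train$i_uA)]
  q <- train$i_uA / train$fs_out * 1e3           # uA-samples -> nC
  data.frame(
    pulse = seq_len(train$n_pulses),
    cathodic_nC = as.numeric(tapply(pmin(q, 0), idx, sum)),
    anodic_nC = as.numeric(tapply(pmax(q, 0), idx, sum)),
    net_nC = as.numeric(tapply(q, idx, sum)))
}

#' Write a stimulation train as CSV
#' @param train A [make_biphasic_train()] result.
#' @param path Output file (columns `t_s`, `i_uA`).
#' @export
write_stim_csv <- function(train, path) {
  utils::write.csv(data.frame(t_s = train$t_s, i_uA = train$i_uA), path,
                   row.names = FALSE)
}

#' Accelerated-aging time equivalence
#'
#' Arrhenius-style Q10 scaling used for elevated-temperature soak tests: a
#' soak at `test_temp_C` for `test_duration_weeks` is equivalent to
#' `test_duration_weeks * q10^((test_temp_C - real_temp_C)/10)` weeks at
#' `real_temp_C`. With the conventional Q10 = 2, 4 weeks at 60 C corresponds
#' to about 20 weeks at body temperature.
#'
#' @param test_temp_C Soak temperature (Celsius).
#' @param real_temp_C Reference (body) temperature, default 37.
#' @param test_duration_weeks Soak duration.
#' @param q10 Aging-rate ratio per 10 C (default 2).
#' @return Equivalent duration in weeks at `real_temp_C`.
#' @export
accelerated_aging_equivalent <- function(test_temp_C, real_temp_C = 37,
                                         test_duration_weeks, q10 = 2) {
  if (!is.finite(test_temp_C) || !is.finite(real_temp_C)) {
    stop("temperatures must be finite", call. = FALSE)
  }
  stopifnot_scalar(test_duration_weeks, "test_duration_weeks")
  if (q10 <= 0) stop("q10 must be positive", call. = FALSE)
  test_duration_weeks * q10^((test_temp_C - real_temp_C) / 10)
}
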