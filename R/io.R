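#' Persist / load EEG trial sets as plain text
#'
#' Trial sets are stored as a long-format CSV (`trial`, `channel`, `sample`,
#' `uV`) plus a JSON sidecar (`<path>.json`) holding the sampling rate,
#' channel names and labels. Plain-text round-tripping keeps datasets
#' portable and diffable; large datasets are better regenerated from their
#' seeds.
#'
#' @param trials List of [eeg_trial()] objects.
#' @param path CSV path; the sidecar is written next to it.
#' @export
write_trials_csv <- function(trials, path) {
  n_ch <- nrow(trials[[1]]$data)
  n_s <- ncol(trials[[1]]$data)
  df <- data.frame(
    trial = rep(seq_along(trials), each = n_ch * n_s),
    channel = rep(rep(seq_len(n_ch), each = n_s), times = length(trials)),
    sample = rep(seq_len(n_s), times = n_ch * length(trials)),
    uV = unlist(lapply(trials, function(tr) as.numeric(t(tr$data)))))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(fs = trials[[1]]$fs,
               channel_names = trials[[1]]$channel_names,
               labels = vapply(trials, function(tr) as.integer(tr$label),
                               integer(1)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
}

#' @rdname write_trials_csv
#' @return `read_trials_csv` returns the list of [eeg_trial()] objects.
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lapply(sort(unique(df$trial)), function(tr) {
    sub <- df[df$trial == tr, ]
    n_ch <- max(sub$channel); n_s <- max(sub$sample)
    m <- matrix(0, n_ch, n_s)
    m[cbind(sub$channel, sub$sample)] <- sub$uV
    eeg_trial(m, meta$fs, meta$channel_names, meta$labels[tr])
  })
}

#' Write training history as CSV
#' @param model A trained decoder.
#' @param path Output CSV (`epoch`, `lr`, `loss`, `train_acc`, `val_acc`).
#' @export
write_history_csv <- function(model, path) {
  utils::write.csv(model$history, path, row.names = FALSE)
}

#' Save / load a decoder checkpoint
#'
#' Single-file archive (R serialization) holding weights, the config
#' snapshot and the training history.
#'
#' @param model A `trained_decoder`.
#' @param path Checkpoint file path.
#' @export
save_decoder <- function(model, path) {
  saveRDS(model, path)
}

#' @rdname save_decoder
#' @export
load_decoder <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "trained_decoder")) {
    stop("file is not a decoder checkpoint", call. = FALSE)
  }
  model
}
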