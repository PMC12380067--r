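# Memoized heavy objects shared across test files (field solves and the
# decoder-scale dataset are expensive; every consumer goes through these).
.test_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .test_cache)) {
    assign(key, force(expr), envir = .test_cache)
  }
  get(key, envir = .test_cache)
}

# unit-current field solutions on the default graded grid
unit_field <- function(kind, refine = 1, glial = NULL) {
  key <- paste0("field_", kind, "_", refine, "_",
                if (is.null(glial)) "d" else glial)
  memo(key, {
    tis <- tissue_model()
    solve_field(build_geometry(kind, tis, glial_thickness_um = glial),
                tis, 1, refine = refine)
  })
}

# quick coarse grid for linearity-style solver tests
coarse_grid <- function(geom) {
  field_grid(geom, fine_um = 12, growth = 1.8)
}

# decoder-scale dataset: 80 train + 40 test trials per class at +10 dB,
# band-filtered, as labelled tensors
decoder_data <- function() {
  memo("decoder_data", {
    spec <- synth_spec(snr_db = 10, seed = 2024L)
    train <- lapply(synth_dataset(80, spec), preprocess_trial)
    spec$seed <- 4048L
    test <- lapply(synth_dataset(40, spec), preprocess_trial)
    list(train = to_tensor(train), test = to_tensor(test))
  })
}

# small dataset for fast training tests: 20 train + 8 test per class
small_decoder_data <- function() {
  memo("small_decoder_data", {
    spec <- synth_spec(snr_db = 10, seed = 77L)
    train <- lapply(synth_dataset(20, spec), preprocess_trial)
    spec$seed <- 78L
    test <- lapply(synth_dataset(8, spec), preprocess_trial)
    list(train = to_tensor(train), test = to_tensor(test))
  })
}

# a briefly trained decoder on the small dataset (shared by feature-quality
# and evaluation tests)
small_trained_decoder <- function() {
  memo("small_trained_decoder", {
    d <- small_decoder_data()
    model <- build_decoder(decoder_config(seed = 5))
    train_decoder(model, d$train, train_config(epochs = 12, seed = 9))
  })
}
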