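# Small, fast configuration for unit tests: 64 Hz, 24 trials, no line
# interference (50 Hz is above this Nyquist). Band structure and trial
# geometry are the defaults.
quick_cfg <- function(...) {
  args <- utils::modifyList(list(fs = 64, n_trials = 24L, line_amp = 0),
                            list(...))
  do.call(sim_config, args)
}

# Build an mi_run directly from a channels x samples matrix, for
# deterministic filter fixtures.
make_run <- function(data, fs, trial_onsets = 1L,
                     labels = factor("left", levels = c("left", "right")),
                     channel_names = paste0("ch", seq_len(nrow(data)))) {
  structure(list(data = data, fs = fs,
                 trial_onsets = as.integer(trial_onsets), labels = labels,
                 channel_names = channel_names,
                 artifact_trials = integer(0), provenance = NULL),
            class = "mi_run")
}

# Single-channel sinusoid run of `secs` seconds.
sine_run <- function(f, fs = 256, secs = 8, amp = 1) {
  t <- (0:(secs * fs - 1)) / fs
  make_run(matrix(amp * sin(2 * pi * f * t), nrow = 1), fs)
}

# FFT amplitude of a signal at frequency f (bins are exact for
# integer-cycle signals).
fft_amp <- function(x, f, fs) {
  n <- length(x)
  abs(stats::fft(x))[round(f * n / fs) + 1] * 2 / n
}

# Build an epoch_set directly from an array.
make_epochs <- function(epochs, labels, fs = 64, band = c(8, 30),
                        channel_names = paste0("ch", seq_len(dim(epochs)[2]))) {
  structure(list(epochs = epochs,
                 labels = factor(labels, levels = c("left", "right")),
                 fs = fs, kept_mask = rep(TRUE, dim(epochs)[1]),
                 band = band, channel_names = channel_names,
                 empty = dim(epochs)[1] == 0),
            class = "epoch_set")
}

# White-noise epochs with per-class, per-channel scaling: class "left"
# channel SDs `sd_left`, class "right" `sd_right`.
scaled_noise_epochs <- function(n_per_class, sd_left, sd_right,
                                n_samp = 512, fs = 64, seed = 1) {
  stopifnot(length(sd_left) == length(sd_right))
  nch <- length(sd_left)
  set.seed(seed)
  n <- 2 * n_per_class
  epochs <- array(rnorm(n * nch * n_samp), dim = c(n, nch, n_samp))
  labels <- rep(c("left", "right"), each = n_per_class)
  for (i in seq_len(n)) {
    s <- if (labels[i] == "left") sd_left else sd_right
    epochs[i, , ] <- epochs[i, , ] * s
  }
  make_epochs(epochs, labels, fs = fs)
}

# Feature block built directly from a trials x timepoints x features
# array.
make_features <- function(values, labels, timepoints = NULL) {
  if (is.null(timepoints)) timepoints <- seq_len(dim(values)[2])
  structure(list(values = values,
                 labels = factor(labels, levels = c("left", "right")),
                 timepoints = timepoints, window_len = 1.5),
            class = "feature_block")
}
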