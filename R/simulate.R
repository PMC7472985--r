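#' Standard 16-channel sensorimotor montage
#'
#' Electrode labels of the extended 10/20 montage used throughout the
#' package, covering premotor (FC), motor (C) and postcentral (CP) rows.
#'
#' @return Character vector of 16 channel names.
#' @export
mi_montage <- function() {
  c("FC5", "FC1", "FCz", "FC2", "FC6",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP5", "CP1", "CP2", "CP6")
}

# Spatial projection of the two lateralized sensorimotor sources:
# weight 1 at the primary electrode (C3 left hemisphere, C4 right),
# 0.5 at its immediate montage neighbours, 0 elsewhere.
source_projection <- function(channel_names = mi_montage()) {
  w <- matrix(0, nrow = 2, ncol = length(channel_names),
              dimnames = list(c("C3", "C4"), channel_names))
  nb <- list(
    C3 = c("C5", "C1", "FC5", "FC1", "CP5", "CP1"),
    C4 = c("C6", "C2", "FC6", "FC2", "CP6", "CP2")
  )
  for (src in rownames(w)) {
    w[src, src] <- 1
    hit <- intersect(nb[[src]], channel_names)
    w[src, hit] <- 0.5
  }
  w
}

#' Simulation configuration for a motor-imagery run
#'
#' Bundles and validates all parameters of the synthetic EEG generator.
#' Defaults reproduce the study conditions of the protocol this package
#' models: 16 channels, 80 trials of 9 s cadence with an 8 s usable
#' epoch, motor imagery from 2 s to 8 s within the trial, mu (8-12 Hz)
#' and beta (18-26 Hz) rhythms attenuated contralaterally during
#' imagery, 1/f background noise, and optional 50 Hz line interference
#' and artifact trials.
#'
#' @param n_channels Number of EEG channels (must match
#'   `channel_names`).
#' @param channel_names Ordered electrode labels.
#' @param fs Sampling rate in Hz. The amplifier rate is not part of the
#'   protocol definition; 256 Hz is typical for this hardware class.
#' @param n_trials Trials per run.
#' @param trial_len Trial cadence in seconds.
#' @param epoch_len Usable epoch length in seconds (`<= trial_len`).
#' @param mi_window Numeric `[start, end]` in seconds within the epoch
#'   during which motor imagery (and hence ERD) is active.
#' @param mu_band,beta_band Rhythm bands in Hz.
#' @param erd_depth Fractional variance attenuation of the contralateral
#'   rhythms during imagery, in `[0, 1]`. 0 means no class difference.
#' @param noise_exponent Spectral slope alpha of the 1/f^alpha
#'   background.
#' @param noise_sd Background noise standard deviation per channel (uV).
#' @param mu_sd,beta_sd Rhythm source standard deviations (uV) at the
#'   primary electrode.
#' @param line_amp Amplitude (uV) of 50 Hz line interference.
#' @param artifact_rate Fraction of trials given a high-amplitude
#'   transient (10 x channel SD step on 2 random channels for 0.5 s).
#' @param class_balance Fraction of left-hand trials, in `(0, 1)`.
#' @param seed Integer seed; identical seeds give bit-identical runs.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_channels = 16L,
                       channel_names = mi_montage(),
                       fs = 256,
                       n_trials = 80L,
                       trial_len = 9.0,
                       epoch_len = 8.0,
                       mi_window = c(2.0, 8.0),
                       mu_band = c(8, 12),
                       beta_band = c(18, 26),
                       erd_depth = 0.6,
                       noise_exponent = 1.0,
                       noise_sd = 5.0,
                       mu_sd = 10.0,
                       beta_sd = 5.0,
                       line_amp = 1.0,
                       artifact_rate = 0.0,
                       class_balance = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_channels = as.integer(n_channels), channel_names = channel_names,
    fs = fs, n_trials = as.integer(n_trials), trial_len = trial_len,
    epoch_len = epoch_len, mi_window = mi_window, mu_band = mu_band,
    beta_band = beta_band, erd_depth = erd_depth,
    noise_exponent = noise_exponent, noise_sd = noise_sd,
    mu_sd = mu_sd, beta_sd = beta_sd, line_amp = line_amp,
    artifact_rate = artifact_rate, class_balance = class_balance,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)
  if (cfg$n_channels != length(cfg$channel_names))
    fail("n_channels must equal length(channel_names)")
  if (cfg$epoch_len > cfg$trial_len)
    fail("epoch_len must be <= trial_len")
  if (cfg$mi_window[1] < 0 || cfg$mi_window[2] > cfg$epoch_len ||
      cfg$mi_window[1] >= cfg$mi_window[2])
    fail("mi_window must lie within [0, epoch_len]")
  if (cfg$erd_depth < 0 || cfg$erd_depth > 1)
    fail("erd_depth must be in [0, 1]")
  if (cfg$class_balance <= 0 || cfg$class_balance >= 1)
    fail("class_balance must be in (0, 1)")
  if (cfg$fs < 2 * cfg$beta_band[2])
    fail("fs must be at least twice the upper beta band edge")
  if (cfg$n_trials < 1) fail("n_trials must be >= 1")
  invisible(cfg)
}

#' ERD gain envelope
#'
#' Amplitude gain applied to a rhythm source as a function of time
#' within the trial: 1 outside the imagery window, `sqrt(1 - erd_depth)`
#' inside (so the *variance* is attenuated by `1 - erd_depth`), with a
#' smooth cosine ramp of width `ramp` seconds at both edges. Times are
#' clamped, so any numeric input is accepted.
#'
#' @param t Time(s) in seconds within the trial (vectorized).
#' @param mi_window Numeric `[start, end]` of the imagery window.
#' @param erd_depth Fractional variance attenuation in `[0, 1]`.
#' @param ramp Ramp width in seconds.
#' @return Gain factor(s) in `[sqrt(1 - erd_depth), 1]`.
#' @export
erd_envelope <- function(t, mi_window, erd_depth, ramp = 0.2) {
  g_in <- sqrt(1 - erd_depth)
  # transition 0 (outside) -> 1 (inside) with half-cosine edges
  up <- pmin(pmax((t - mi_window[1]) / max(ramp, 1e-9), 0), 1)
  dn <- pmin(pmax((mi_window[2] - t) / max(ramp, 1e-9), 0), 1)
  s <- (1 - cos(pi * up)) / 2 * (1 - cos(pi * dn)) / 2
  1 + s * (g_in - 1)
}

# Run the expression with a local, seeded RNG; the caller's RNG state
# is untouched.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 1/f^alpha Gaussian noise of length n, unit variance, via spectral
# shaping of white noise.
pink_noise <- function(n, fs, alpha) {
  x <- stats::rnorm(n)
  if (alpha == 0) return(x)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]       # two-sided frequency axis
  shape <- c(0, pmax(f[-1], fs / n)^(-alpha / 2))
  y <- Re(stats::fft(stats::fft(x) * shape, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Band-limited Gaussian rhythm: white noise band-passed to [low, high],
# rescaled to unit variance.
band_rhythm <- function(n, fs, band) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, stats::rnorm(n))
  y / stats::sd(y)
}

#' Simulate one motor-imagery EEG run
#'
#' Generates a continuous multi-channel recording with the statistical
#' structure the decoding chain assumes: two lateralized sensorimotor
#' sources (mu + beta rhythms over C3 and over C4) superposed on
#' independent 1/f background noise per channel, with the source
#' contralateral to the imagined hand attenuated by `erd_depth`
#' (variance) during the imagery window of each trial. Optionally adds
#' common 50 Hz line interference and high-amplitude artifact trials.
#'
#' The class sequence is a seeded random permutation of a balanced
#' left/right assignment (`round(n_trials * class_balance)` left
#' trials).
#'
#' @param config A [sim_config()].
#' @return An object of class `mi_run`: list with `data` (channels x
#'   samples matrix, uV), `fs`, `trial_onsets` (1-based sample indices),
#'   `labels` (factor, levels `left`/`right`), `channel_names`,
#'   `artifact_trials` (ground-truth injected artifacts) and
#'   `provenance` (the config).
#' @export
simulate_run <- function(config) {
  validate_sim_config(config)
  cfg <- config
  with_local_seed(cfg$seed, {
    fs <- cfg$fs
    spt <- round(cfg$trial_len * fs)            # samples per trial
    n <- cfg$n_trials * spt
    nch <- cfg$n_channels

    n_left <- round(cfg$n_trials * cfg$class_balance)
    labels <- factor(sample(rep(c("left", "right"),
                                c(n_left, cfg$n_trials - n_left))),
                     levels = c("left", "right"))
    trial_onsets <- as.integer((seq_len(cfg$n_trials) - 1L) * spt + 1L)

    # background: independent 1/f noise per channel
    data <- matrix(0, nrow = nch, ncol = n,
                   dimnames = list(cfg$channel_names, NULL))
    for (ch in seq_len(nch))
      data[ch, ] <- cfg$noise_sd * pink_noise(n, fs, cfg$noise_exponent)

    # lateralized rhythm sources with per-sample ERD gain:
    # source "C3" (left hemisphere) attenuates during right-hand MI,
    # source "C4" during left-hand MI.
    proj <- source_projection(cfg$channel_names)
    t_in_trial <- (seq_len(spt) - 1) / fs
    env_active <- erd_envelope(t_in_trial, cfg$mi_window, cfg$erd_depth)
    gain <- list(C3 = rep(1, n), C4 = rep(1, n))
    for (i in seq_len(cfg$n_trials)) {
      idx <- trial_onsets[i]:(trial_onsets[i] + spt - 1L)
      src <- if (labels[i] == "right") "C3" else "C4"
      gain[[src]][idx] <- env_active
    }
    for (src in c("C3", "C4")) {
      rhythm <- cfg$mu_sd * band_rhythm(n, fs, cfg$mu_band) +
        cfg$beta_sd * band_rhythm(n, fs, cfg$beta_band)
      data <- data + outer(proj[src, ], rhythm * gain[[src]])
    }

    # common-mode line interference
    if (cfg$line_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      line <- cfg$line_amp * sin(2 * pi * 50 * (seq_len(n) - 1) / fs + phase)
      data <- sweep(data, 2, line, `+`)
    }

    # artifact trials: 10 x channel SD amplitude step on 2 random
    # channels for 0.5 s, placed inside the epoch
    n_art <- round(cfg$artifact_rate * cfg$n_trials)
    artifact_trials <- integer(0)
    if (n_art > 0) {
      artifact_trials <- sort(sample(cfg$n_trials, n_art))
      ch_sd <- apply(data, 1, stats::sd)
      for (i in artifact_trials) {
        chs <- sample(nch, 2)
        start <- trial_onsets[i] + round(stats::runif(1, 0.5, cfg$epoch_len - 1) * fs)
        idx <- start:(start + round(0.5 * fs) - 1L)
        data[chs, idx] <- data[chs, idx] + 10 * ch_sd[chs]
      }
    }

    structure(list(data = data, fs = fs, trial_onsets = trial_onsets,
                   labels = labels, channel_names = cfg$channel_names,
                   artifact_trials = artifact_trials, provenance = cfg),
              class = "mi_run")
  })
}

#' @export
print.mi_run <- function(x, ...) {
  cat(sprintf("<mi_run> %d channels x %d samples @ %g Hz, %d trials (%d left / %d right)\n",
              nrow(x$data), ncol(x$data), x$fs, length(x$labels),
              sum(x$labels == "left"), sum(x$labels == "right")))
  invisible(x)
}

#' Write / read a run as CSV + JSON sidecar
#'
#' The CSV holds samples x channels with a header of channel names, at
#' 9 significant digits; the JSON sidecar carries `fs`, `trial_onsets`,
#' `labels` and the generating configuration. Reading back a written
#' pair and writing it again is byte-identical (lossless at the stated
#' precision).
#'
#' @param run An `mi_run`.
#' @param path Base path; `<path>.csv` and `<path>.json` are written.
#' @return `write_run`: `path`, invisibly. `read_run`: an `mi_run`.
#' @export
write_run <- function(run, path) {
  m <- signif(t(run$data), 9)
  utils::write.csv(m, paste0(path, ".csv"), row.names = FALSE)
  meta <- list(fs = run$fs, trial_onsets = run$trial_onsets,
               labels = as.character(run$labels),
               channel_names = run$channel_names,
               artifact_trials = run$artifact_trials,
               provenance = unclass(run$provenance))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run
#' @export
read_run <- function(path) {
  m <- utils::read.csv(paste0(path, ".csv"), check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  prov <- meta$provenance
  if (!is.null(prov)) class(prov) <- "sim_config"
  structure(list(data = t(as.matrix(m)), fs = meta$fs,
                 trial_onsets = as.integer(meta$trial_onsets),
                 labels = factor(meta$labels, levels = c("left", "right")),
                 channel_names = meta$channel_names,
                 artifact_trials = as.integer(meta$artifact_trials),
                 provenance = prov),
            class = "mi_run")
}
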