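#' Default gesture activation profiles
#'
#' The ten hand gestures used throughout the package, each with a fixed
#' 16-channel activation vector describing how strongly the gesture drives
#' each electrode pair of a 16-channel forearm armband. Each gesture excites
#' a localized group of channels (a smooth bump centred on a different part
#' of the forearm circumference, plus a small co-activation baseline), so
#' classes are spatially distinct: all pairwise cosine similarities between
#' activation vectors are below 0.95.
#'
#' @return A tibble with one row per gesture and columns `gesture_id`
#'   (integer 0-9), `name`, and `activation` (list column of length-16
#'   non-negative weight vectors).
#' @examples
#' gesture_profiles()
#' @export
gesture_profiles <- function() {
  names10 <- c(
    "Power Grip", "OK Hand", "Thumb Up", "Thumb Down", "Scissorhands",
    "Palm Up", "Palm Down", "Palm Outward", "Palm to the left",
    "Palm to the right"
  )
  channels <- 0:15
  activation <- lapply(0:9, function(g) {
    centre <- 0.5 + 1.6 * g           # evenly spaced around the armband
    bump <- exp(-(channels - centre)^2 / (2 * 1.2^2))
    # wrap-around: the armband is a ring, channel 15 neighbours channel 0
    bump <- bump + exp(-(channels - centre - 16)^2 / (2 * 1.2^2)) +
      exp(-(channels - centre + 16)^2 / (2 * 1.2^2))
    w <- bump / max(bump) + 0.05
    round(w, 6)
  })
  tibble(
    gesture_id = 0:9,
    name = names10,
    activation = activation
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic sEMG generator. Defaults mirror the armband
#' acquisition protocol the pipeline is designed around: 2000 samples/s,
#' 16 channels, 10 s gesture holds separated by 3 s rests, 10 repetitions
#' per gesture. The EMG carrier is Gaussian noise band-limited to the
#' typical surface-EMG energy band (20-450 Hz) and normalized to unit RMS,
#' so `powerline_amp`, `dc_offset` and `noise_rms` are all expressed
#' relative to unit signal amplitude.
#'
#' @param fs sampling rate, samples/s per channel.
#' @param n_channels number of electrode channels, 8 or 16.
#' @param hold_duration gesture hold length in seconds.
#' @param rest_duration rest between repetitions in seconds (protocol
#'   metadata; rests are not synthesized).
#' @param n_repetitions repetitions of each gesture per subject.
#' @param n_subjects number of subjects.
#' @param emg_band numeric length-2, pass band (Hz) of the EMG carrier.
#' @param powerline_amp amplitude of the 50 Hz mains interference.
#' @param dc_offset constant offset added to every channel.
#' @param noise_rms RMS of additive white measurement noise.
#' @param seed integer master seed; every recording derives its own stream
#'   from it.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' sim_config(n_subjects = 2, hold_duration = 2.5)
#' @export
sim_config <- function(fs = 2000, n_channels = 16, hold_duration = 10,
                       rest_duration = 3, n_repetitions = 10,
                       n_subjects = 30, emg_band = c(20, 450),
                       powerline_amp = 0.5, dc_offset = 0.3,
                       noise_rms = 0.05, seed = 1L) {
  stopifnot_scalar_num(fs, "fs")
  stopifnot_scalar_num(hold_duration, "hold_duration")
  stopifnot_scalar_num(rest_duration, "rest_duration", positive = FALSE)
  stopifnot_scalar_num(n_repetitions, "n_repetitions")
  stopifnot_scalar_num(n_subjects, "n_subjects")
  if (!n_channels %in% c(8L, 16L)) {
    abort("`n_channels` must be 8 or 16.")
  }
  if (length(emg_band) != 2 || !all(is.finite(emg_band)) ||
      emg_band[1] <= 0 || emg_band[1] >= emg_band[2] ||
      emg_band[2] >= fs / 2) {
    abort("`emg_band` must satisfy 0 < low < high < fs/2.")
  }
  for (amp in c(powerline_amp, dc_offset, noise_rms)) {
    if (!is.finite(amp) || amp < 0) abort("amplitudes must be finite and >= 0.")
  }
  structure(
    list(
      fs = fs, n_channels = as.integer(n_channels),
      hold_duration = hold_duration, rest_duration = rest_duration,
      n_repetitions = as.integer(n_repetitions),
      n_subjects = as.integer(n_subjects),
      emg_band = as.numeric(emg_band), powerline_amp = powerline_amp,
      dc_offset = dc_offset, noise_rms = noise_rms, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Channels retained for the 8-channel condition: 0-based even indices of the
# 16-channel montage, i.e. every other electrode around the armband.
channels_8 <- function() seq(1L, 15L, by = 2L)

new_recording <- function(samples, fs, gesture_id, subject_id, repetition) {
  structure(
    list(
      samples = samples, fs = fs, gesture_id = as.integer(gesture_id),
      subject_id = as.integer(subject_id), repetition = as.integer(repetition)
    ),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording> %d channels x %d samples @ %g sps | gesture %d, subject %d, rep %d\n",
    nrow(x$samples), ncol(x$samples), x$fs, x$gesture_id, x$subject_id,
    x$repetition
  ))
  invisible(x)
}

# Raised-cosine onset/offset envelope over the hold; 0.25 s ramps (shorter
# for very short holds) around a unit plateau, so filter transients at the
# contraction boundary stay smooth.
hold_envelope <- function(n, fs, ramp_s = 0.25) {
  t <- seq_len(n) / fs
  total <- n / fs
  ramp <- min(ramp_s, total / 4)
  e <- rep(1, n)
  up <- t < ramp
  e[up] <- 0.5 * (1 - cos(pi * t[up] / ramp))
  down <- t > total - ramp
  e[down] <- 0.5 * (1 - cos(pi * (total - t[down]) / ramp))
  e
}

# Gaussian white noise band-passed to `band` and scaled to unit RMS.
bandlimited_carrier <- function(n, fs, band) {
  x <- stats::rnorm(n)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  y <- filtfilt_refl(bf$b, bf$a, x)
  y / stats::sd(y)
}

#' Simulate one labeled sEMG recording
#'
#' Generates the hold phase of a single gesture repetition. Per channel the
#' signal is `activation[c] * envelope(t) * carrier_c(t)` (independent
#' unit-RMS band-limited Gaussian carriers), plus a shared 50 Hz powerline
#' sinusoid with a per-recording random phase, a constant DC offset, and
#' white measurement noise. A fixed multiplicative lognormal perturbation
#' (sigma = 0.15), drawn from a subject-derived seed, models inter-subject
#' electrode and anatomy variation and is identical across that subject's
#' repetitions.
#'
#' @param profile one row of [gesture_profiles()] (or a list with
#'   `gesture_id`, `name`, `activation`).
#' @param cfg a [sim_config()].
#' @param subject_id,repetition integer provenance labels.
#' @param seed optional integer; defaults to a stream derived from
#'   `cfg$seed` and the (gesture, subject, repetition) triple. Identical
#'   seeds give bit-identical recordings.
#' @return An `emg_recording`: `samples` is an `n_channels x n_samples`
#'   matrix, with `fs`, `gesture_id`, `subject_id`, `repetition` attached.
#' @examples
#' rec <- simulate_recording(gesture_profiles()[1, ],
#'   sim_config(hold_duration = 0.5), subject_id = 1, repetition = 1)
#' dim(rec$samples)
#' @export
simulate_recording <- function(profile, cfg = sim_config(), subject_id = 1L,
                               repetition = 1L, seed = NULL) {
  if (is.data.frame(profile)) {
    stopifnot(nrow(profile) == 1)
    profile <- list(
      gesture_id = profile$gesture_id[[1]], name = profile$name[[1]],
      activation = profile$activation[[1]]
    )
  }
  if (!inherits(cfg, "sim_config")) abort("`cfg` must be a sim_config().")
  gid <- profile$gesture_id
  if (!is.numeric(gid) || length(gid) != 1 || gid < 0 || gid > 9 ||
      gid != round(gid)) {
    abort("`gesture_id` must be an integer in 0..9.")
  }
  act <- as.numeric(profile$activation)
  if (length(act) != 16 || any(!is.finite(act)) || any(act < 0)) {
    abort("`activation` must be 16 finite non-negative weights.")
  }
  seed <- seed %||% derive_seed(cfg$seed, gid, subject_id, repetition)

  # subject-specific electrode/anatomy factors, constant across repetitions
  jitter <- with_seed(
    derive_seed(cfg$seed, 900001L, subject_id),
    exp(stats::rnorm(16, mean = 0, sd = 0.15))
  )
  act <- act * jitter
  keep <- if (cfg$n_channels == 8L) channels_8() else 1:16
  act <- act[keep]

  n <- round(cfg$fs * cfg$hold_duration)
  t <- seq_len(n) / cfg$fs
  env <- hold_envelope(n, cfg$fs)

  samples <- with_seed(seed, {
    phi <- stats::runif(1, 0, 2 * pi)
    line <- cfg$powerline_amp * sin(2 * pi * 50 * t + phi)
    m <- matrix(0, nrow = cfg$n_channels, ncol = n)
    for (c in seq_len(cfg$n_channels)) {
      emg <- if (act[c] > 0) {
        act[c] * env * bandlimited_carrier(n, cfg$fs, cfg$emg_band)
      } else {
        numeric(n)
      }
      noise <- if (cfg$noise_rms > 0) cfg$noise_rms * stats::rnorm(n) else 0
      m[c, ] <- emg + line + cfg$dc_offset + noise
    }
    m
  })
  new_recording(samples, cfg$fs, gid, subject_id, repetition)
}

#' Simulate a full labeled dataset
#'
#' Runs the acquisition protocol for every (subject, gesture, repetition)
#' cell: `cfg$n_subjects` subjects each hold every gesture
#' `cfg$n_repetitions` times, giving a class-balanced dataset. Fully
#' deterministic for a fixed `cfg$seed`.
#'
#' @param profiles tibble of gesture profiles (default [gesture_profiles()]);
#'   at least 2 rows, gesture ids must be unique.
#' @param cfg a [sim_config()].
#' @return A tibble with columns `gesture_id`, `name`, `subject_id`,
#'   `repetition`, and `recording` (list column of `emg_recording`).
#' @examples
#' d <- simulate_dataset(gesture_profiles()[1:2, ],
#'   sim_config(n_subjects = 1, n_repetitions = 2, hold_duration = 0.25))
#' nrow(d)
#' @export
simulate_dataset <- function(profiles = gesture_profiles(),
                             cfg = sim_config()) {
  if (!is.data.frame(profiles) || nrow(profiles) < 2) {
    abort("`profiles` must contain at least 2 gesture profiles.")
  }
  if (anyDuplicated(profiles$gesture_id)) {
    abort("duplicate `gesture_id` values in `profiles`.")
  }
  grid <- tidyr::expand_grid(
    subject_id = seq_len(cfg$n_subjects),
    gesture_id = profiles$gesture_id,
    repetition = seq_len(cfg$n_repetitions)
  )
  grid |>
    dplyr::left_join(profiles[, c("gesture_id", "name")], by = "gesture_id") |>
    dplyr::mutate(
      recording = purrr::pmap(
        list(.data$gesture_id, .data$subject_id, .data$repetition),
        function(g, s, r) {
          simulate_recording(
            profiles[match(g, profiles$gesture_id), ], cfg,
            subject_id = s, repetition = r
          )
        }
      )
    ) |>
    dplyr::select("gesture_id", "name", "subject_id", "repetition",
                  "recording")
}
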