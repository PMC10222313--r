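# Small fixtures shared across test files. Everything is generated in code;
# sizes are kept tiny so the whole suite stays fast.

tiny_sim_config <- function(hold = 1, subjects = 1, reps = 2, seed = 42,
                            ...) {
  sim_config(n_subjects = subjects, n_repetitions = reps,
             hold_duration = hold, seed = seed, ...)
}

# one 16-channel recording of `hold` seconds
tiny_recording <- function(gesture = 0, hold = 1, seed = 42, ...) {
  simulate_recording(gesture_profiles()[gesture + 1, ],
                     tiny_sim_config(hold = hold, seed = seed, ...),
                     subject_id = 1, repetition = 1)
}

# wrap a plain matrix as a recording (for filter tests on known signals)
as_recording <- function(m, fs = 2000, gesture_id = 0) {
  structure(
    list(samples = m, fs = fs, gesture_id = as.integer(gesture_id),
         subject_id = 1L, repetition = 1L),
    class = "emg_recording"
  )
}

rms <- function(x) sqrt(mean(x^2))

# raw periodogram power at each FFT bin of a vector
periodogram <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  k <- 0:(n %/% 2)
  data.frame(freq = k * fs / n, power = p[k + 1])
}

# wrap a pixel matrix as an emg_image (for model tests on synthetic pixels)
as_image <- function(pixels, label = 0L, encoder = "spectrogram",
                     subject_id = 1L, repetition = 1L, segment = 1L) {
  structure(
    list(pixels = pixels, encoder = encoder,
         n_channels_source = 16L, label = as.integer(label),
         subject_id = as.integer(subject_id),
         repetition = as.integer(repetition), segment = as.integer(segment)),
    class = "emg_image"
  )
}
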