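#' Windowing specification for segmentation and STFT framing
#'
#' One classification record is a 250 ms segment; inside a segment the STFT
#' slides a 100 ms analysis window by 50 ms increments. These are the
#' defaults; all durations must correspond to whole sample counts at the
#' sampling rate in use.
#'
#' @param segment_ms segment (classification record) length, ms.
#' @param window_ms STFT analysis window length, ms.
#' @param hop_ms STFT window increment, ms.
#' @return A `window_spec` object.
#' @export
window_spec <- function(segment_ms = 250, window_ms = 100, hop_ms = 50) {
  if (!(segment_ms > 0 && window_ms > 0 && hop_ms > 0)) {
    abort("all durations must be > 0.")
  }
  if (window_ms > segment_ms) abort("`window_ms` must be <= `segment_ms`.")
  if (hop_ms > window_ms) abort("`hop_ms` must be <= `window_ms`.")
  structure(list(segment_ms = segment_ms, window_ms = window_ms,
                 hop_ms = hop_ms), class = "window_spec")
}

#' STFT specification
#'
#' Hann-windowed one-sided short-time Fourier transform. `nfft = 256` is
#' the next power of two above the 200-sample analysis window at 2000
#' samples/s and yields `256/2 + 1 = 129` frequency bins.
#'
#' @param nfft FFT length; a power of two at least as long as the analysis
#'   window in samples.
#' @param log_magnitude use `log1p` of the magnitude instead of linear
#'   magnitude when forming spectrogram pixels.
#' @return An `stft_spec` object.
#' @export
stft_spec <- function(nfft = 256, log_magnitude = FALSE) {
  if (nfft < 2 || bitwAnd(as.integer(nfft), as.integer(nfft) - 1L) != 0L) {
    abort("`nfft` must be a power of two.")
  }
  structure(list(nfft = as.integer(nfft),
                 log_magnitude = isTRUE(log_magnitude)),
            class = "stft_spec")
}

ms_to_samples <- function(ms, fs) {
  n <- ms * fs / 1000
  if (abs(n - round(n)) > 1e-8) {
    abort(sprintf("%g ms is not a whole number of samples at %g sps.", ms, fs))
  }
  as.integer(round(n))
}

#' Cut a recording into non-overlapping classification segments
#'
#' Consecutive, non-overlapping segments (default 250 ms) are extracted
#' from the hold; any trailing remainder shorter than one segment is
#' dropped. Each segment inherits the recording's gesture label and
#' provenance. The finer 100/50 ms sliding window operates *within* a
#' segment during STFT framing, not here, so segments never share samples
#' and a train/test split by segment cannot leak.
#'
#' @param rec an `emg_recording`.
#' @param w a [window_spec()].
#' @return A tibble with columns `segment` (index), `samples` (list column
#'   of `n_channels x segment_samples` matrices), `gesture_id`,
#'   `subject_id`, `repetition`. Zero rows (with a warning) if the
#'   recording is shorter than one segment.
#' @examples
#' rec <- simulate_recording(gesture_profiles()[1, ],
#'   sim_config(hold_duration = 1), 1, 1)
#' nrow(segment_recording(rec))  # 4 segments of 250 ms
#' @export
segment_recording <- function(rec, w = window_spec()) {
  check_recording(rec)
  seg_n <- ms_to_samples(w$segment_ms, rec$fs)
  total <- ncol(rec$samples)
  k <- total %/% seg_n
  if (k == 0) {
    warn("recording shorter than one segment; returning 0 segments.")
    return(tibble(segment = integer(), samples = list(),
                  gesture_id = integer(), subject_id = integer(),
                  repetition = integer()))
  }
  segs <- lapply(seq_len(k), function(i) {
    rec$samples[, ((i - 1) * seg_n + 1):(i * seg_n), drop = FALSE]
  })
  tibble(
    segment = seq_len(k), samples = segs, gesture_id = rec$gesture_id,
    subject_id = rec$subject_id, repetition = rec$repetition
  )
}

# Symmetric Hann (raised-cosine) taper of length n.
hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

#' STFT magnitude frames of one channel segment
#'
#' Slides a Hann window of `window_ms` by `hop_ms` through the segment
#' (no zero padding at the edges), zero-pads each frame to `nfft` points,
#' and returns one-sided magnitude spectra. At the defaults (250 ms segment,
#' 100 ms window, 50 ms hop, 2000 sps, nfft 256) this is the 4 x 129
#' matrix of frames x frequency bins.
#'
#' @param x numeric vector, one channel of one segment.
#' @param w a [window_spec()].
#' @param s an [stft_spec()].
#' @param fs sampling rate, Hz.
#' @return A numeric matrix `[frames x (nfft/2 + 1)]` of magnitudes.
#' @examples
#' dim(stft_frames(sin(2 * pi * 50 * (1:500) / 2000)))  # 4 x 129
#' @export
stft_frames <- function(x, w = window_spec(), s = stft_spec(), fs = 2000) {
  win_n <- ms_to_samples(w$window_ms, fs)
  hop_n <- ms_to_samples(w$hop_ms, fs)
  seg_n <- ms_to_samples(w$segment_ms, fs)
  if (length(x) != seg_n) {
    abort(sprintf("segment has %d samples; expected %d.", length(x), seg_n))
  }
  if (s$nfft < win_n) abort("`nfft` must be >= the window length in samples.")
  taper <- hann_window(win_n)
  n_frames <- (seg_n - win_n) %/% hop_n + 1L
  bins <- s$nfft / 2 + 1L
  out <- matrix(0, nrow = n_frames, ncol = bins)
  for (f in seq_len(n_frames)) {
    frame <- x[((f - 1) * hop_n + 1):((f - 1) * hop_n + win_n)] * taper
    spec <- stats::fft(c(frame, numeric(s$nfft - win_n)))
    out[f, ] <- Mod(spec[1:bins])
  }
  out
}

new_emg_image <- function(pixels, encoder, n_channels_source, label = NA_integer_,
                          subject_id = NA_integer_, repetition = NA_integer_,
                          segment = NA_integer_) {
  structure(
    list(pixels = pixels, encoder = encoder,
         n_channels_source = as.integer(n_channels_source),
         label = as.integer(label), subject_id = as.integer(subject_id),
         repetition = as.integer(repetition), segment = as.integer(segment)),
    class = "emg_image"
  )
}

#' @export
print.emg_image <- function(x, ...) {
  cat(sprintf("<emg_image> %s, %d x %d pixels, %d source channels, label %s\n",
              x$encoder, nrow(x$pixels), ncol(x$pixels), x$n_channels_source,
              x$label))
  invisible(x)
}

#' Min-max grayscale normalization
#'
#' Rescales a real matrix to `[0, 1]` by `(x - min) / (max - min)`; a
#' constant matrix maps to all zeros. "Constant" is judged with a relative
#' tolerance (1e-12 of the magnitude), so floating-point ripple on a flat
#' signal is not inflated to full contrast.
#'
#' @param m numeric matrix with finite entries.
#' @return A matrix of the same shape with values in `[0, 1]`.
#' @examples
#' to_grayscale(matrix(c(0, 1, 2, 4), 2, byrow = TRUE))
#' @export
to_grayscale <- function(m) {
  if (any(!is.finite(m))) abort("matrix contains non-finite entries.")
  rng <- range(m)
  if (rng[2] - rng[1] <= 1e-12 * max(abs(rng), 1)) {
    return(array(0, dim = dim(m)))
  }
  (m - rng[1]) / (rng[2] - rng[1])
}

#' Append the pointwise cross-channel maximum as an auxiliary channel
#'
#' The feature-enhanced encoding derives one extra signal whose sample at
#' time t is the maximum over all channels at t, and appends it as a final
#' row: 8-channel segments become 9-channel, 16-channel become 17-channel.
#'
#' @param segment numeric matrix `[8 or 16 x n]`.
#' @return A matrix with one extra final row; original rows untouched.
#' @examples
#' augment_max_channel(matrix(1:16, nrow = 8))
#' @export
augment_max_channel <- function(segment) {
  if (!is.matrix(segment) || !nrow(segment) %in% c(8L, 16L)) {
    abort("`segment` must have 8 or 16 channels.")
  }
  rbind(segment, apply(segment, 2, max))
}

#' Encode a segment as a time-domain grayscale image
#'
#' Each channel is low-pass filtered (zero-phase Butterworth at 90% of the
#' post-decimation Nyquist) and decimated by 2, mapping a 500-sample
#' (250 ms at 2000 sps) segment to 250 columns; rows are channels, so 16-
#' and 8-channel segments give 16 x 250 and 8 x 250 images. Pixels are
#' min-max normalized per image.
#'
#' @param segment numeric matrix `[8 or 16 x segment_samples]` with an even
#'   number of columns.
#' @param fs sampling rate, Hz.
#' @param label,subject_id,repetition,segment_index provenance carried on
#'   the image.
#' @return An `emg_image` with `encoder = "time_domain"`.
#' @export
encode_time_domain <- function(segment, fs = 2000, label = NA, subject_id = NA,
                               repetition = NA, segment_index = NA) {
  if (!is.matrix(segment) || !nrow(segment) %in% c(8L, 16L)) {
    abort("time-domain encoding expects 8 or 16 channels.")
  }
  if (ncol(segment) %% 2 != 0) abort("segment length must be even.")
  bf <- signal::butter(4, 0.45)   # anti-alias before decimation by 2
  dec <- t(apply(segment, 1, function(x) {
    filtfilt_refl(bf$b, bf$a, x)[seq(1, length(x), by = 2)]
  }))
  new_emg_image(to_grayscale(dec), "time_domain", nrow(segment), label,
                subject_id, repetition, segment_index)
}

#' Encode a segment as a stacked spectrogram image
#'
#' Computes the per-channel STFT magnitude matrix (4 x 129 at the
#' defaults) and stacks the matrices row-wise in channel order, giving
#' `4 * C x 129` pixels: 32 x 129 for 8 channels, 64 x 129 for 16, and
#' 36 x 129 / 68 x 129 for the 9-/17-channel feature-enhanced segments,
#' whose encoder tag becomes `"enhanced_spectrogram"`. Pixels are min-max
#' normalized per image.
#'
#' @param segment numeric matrix `[C x segment_samples]`, C in 8, 9, 16, 17
#'   (9 and 17 produced by [augment_max_channel()]).
#' @param w a [window_spec()].
#' @param s an [stft_spec()].
#' @inheritParams encode_time_domain
#' @return An `emg_image`.
#' @export
encode_spectrogram <- function(segment, w = window_spec(), s = stft_spec(),
                               fs = 2000, label = NA, subject_id = NA,
                               repetition = NA, segment_index = NA) {
  if (!is.matrix(segment) || !nrow(segment) %in% c(8L, 9L, 16L, 17L)) {
    abort("spectrogram encoding expects 8, 9, 16 or 17 channels.")
  }
  stacked <- do.call(rbind, lapply(seq_len(nrow(segment)), function(c) {
    stft_frames(segment[c, ], w, s, fs)
  }))
  if (s$log_magnitude) stacked <- log1p(stacked)
  enc <- if (nrow(segment) %in% c(9L, 17L)) "enhanced_spectrogram" else "spectrogram"
  new_emg_image(to_grayscale(stacked), enc, nrow(segment), label, subject_id,
                repetition, segment_index)
}

#' Encode a whole dataset of recordings into images
#'
#' Segments every recording into non-overlapping 250 ms records and applies
#' one of the three encoders. The 8-channel condition takes every other
#' electrode (0-based even channels) of the 16-channel montage.
#'
#' @param data tibble from [simulate_dataset()] / [preprocess_dataset()].
#' @param encoder `"time_domain"`, `"spectrogram"` or
#'   `"enhanced_spectrogram"`.
#' @param n_channels 8 or 16 source channels.
#' @param w,s windowing and STFT specifications.
#' @return A tibble with columns `gesture_id`, `subject_id`, `repetition`,
#'   `segment`, and `image` (list column of `emg_image`).
#' @export
encode_dataset <- function(data,
                           encoder = c("time_domain", "spectrogram",
                                       "enhanced_spectrogram"),
                           n_channels = 16, w = window_spec(),
                           s = stft_spec()) {
  encoder <- match.arg(encoder)
  if (!n_channels %in% c(8L, 16L)) abort("`n_channels` must be 8 or 16.")
  segs <- dplyr::bind_rows(purrr::map(data$recording, function(rec) {
    if (n_channels == 8L && nrow(rec$samples) == 16L) {
      rec$samples <- rec$samples[channels_8(), , drop = FALSE]
    } else if (nrow(rec$samples) != n_channels) {
      abort("recording does not supply the requested channel count.")
    }
    segment_recording(rec, w)
  }))
  segs$image <- purrr::pmap(
    list(segs$samples, segs$gesture_id, segs$subject_id, segs$repetition,
         segs$segment),
    function(m, g, sub, rep, idx) {
      switch(encoder,
        time_domain = encode_time_domain(m, fs = data$recording[[1]]$fs,
          label = g, subject_id = sub, repetition = rep, segment_index = idx),
        spectrogram = encode_spectrogram(m, w, s, fs = data$recording[[1]]$fs,
          label = g, subject_id = sub, repetition = rep, segment_index = idx),
        enhanced_spectrogram = encode_spectrogram(augment_max_channel(m), w, s,
          fs = data$recording[[1]]$fs, label = g, subject_id = sub,
          repetition = rep, segment_index = idx)
      )
    }
  )
  segs |>
    dplyr::select("gesture_id", "subject_id", "repetition", "segment",
                  "image")
}
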