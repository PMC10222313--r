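#' Filter specification
#'
#' Parameters for the software noise-reduction chain: a Butterworth
#' band-stop notch for 50 Hz mains interference (stop band 49-51 Hz by
#' default), a single-pole recursive high-pass that removes residual DC
#' offset (cutoff 2 Hz, mirroring the acquisition front end), and an
#' optional Butterworth band-limit.
#'
#' @param kind one of `"notch"`, `"dc_block"`, `"band_limit"`.
#' @param fc1,fc2 lower/upper cutoff in Hz (notch and band_limit).
#' @param order overall Butterworth order (even; the band-stop/band-pass
#'   prototype uses `order/2` poles per edge). Default 4.
#' @param dc_cutoff single-pole high-pass cutoff in Hz.
#' @param zero_phase apply forward-backward for zero phase distortion
#'   (default `TRUE`; ignored by the causal `dc_block`).
#' @return A `filter_spec` object.
#' @examples
#' filter_spec("notch")
#' filter_spec("dc_block", dc_cutoff = 2)
#' @export
filter_spec <- function(kind = c("notch", "dc_block", "band_limit"),
                        fc1 = 49, fc2 = 51, order = 4, dc_cutoff = 2,
                        zero_phase = TRUE) {
  kind <- match.arg(kind)
  if (!is.finite(fc1) || !is.finite(fc2) || fc1 <= 0 || fc1 >= fc2) {
    abort("need 0 < fc1 < fc2.")
  }
  if (order < 1 || order %% 2 != 0) abort("`order` must be an even integer >= 2.")
  if (dc_cutoff <= 0) abort("`dc_cutoff` must be > 0.")
  structure(
    list(kind = kind, fc1 = fc1, fc2 = fc2, order = as.integer(order),
         dc_cutoff = dc_cutoff, zero_phase = isTRUE(zero_phase)),
    class = "filter_spec"
  )
}

# Design the IIR coefficients for a spec at sampling rate fs.
design_filter <- function(spec, fs) {
  switch(spec$kind,
    notch = {
      if (spec$fc2 >= fs / 2) abort("notch `fc2` must be below fs/2.")
      bf <- signal::butter(spec$order / 2, c(spec$fc1, spec$fc2) / (fs / 2),
                           type = "stop")
      list(b = bf$b, a = bf$a)
    },
    band_limit = {
      if (spec$fc2 >= fs / 2) abort("band_limit `fc2` must be below fs/2.")
      bf <- signal::butter(spec$order / 2, c(spec$fc1, spec$fc2) / (fs / 2),
                           type = "pass")
      list(b = bf$b, a = bf$a)
    },
    dc_block = {
      if (spec$dc_cutoff >= fs / 2) abort("`dc_cutoff` must be below fs/2.")
      r <- exp(-2 * pi * spec$dc_cutoff / fs)
      list(b = c(1, -1), a = c(1, -r))
    }
  )
}

# Zero-phase IIR filtering with reflective padding: the signal is extended
# at both ends by its own reflection before the forward and backward passes,
# suppressing startup transients that would otherwise dominate short
# segments. Linear in the input.
filtfilt_refl <- function(b, a, x) {
  n <- length(x)
  pad <- min(30L * (max(length(a), length(b)) - 1L), n - 1L)
  if (pad > 0) {
    head_ext <- 2 * x[1] - x[seq(pad + 1, 2)]
    tail_ext <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xe <- c(head_ext, x, tail_ext)
  } else {
    xe <- x
  }
  y <- as.numeric(signal::filter(b, a, xe))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[seq(pad + 1, pad + n)]
}

apply_channelwise <- function(rec, fun) {
  out <- rec
  out$samples <- t(apply(rec$samples, 1, fun))
  if (ncol(rec$samples) == 1) out$samples <- t(out$samples) # apply() quirk
  out
}

check_recording <- function(rec) {
  if (!inherits(rec, "emg_recording")) abort("`rec` must be an emg_recording.")
  if (ncol(rec$samples) == 0) abort("recording has 0 samples.")
  if (any(!is.finite(rec$samples))) abort("recording contains non-finite samples.")
  invisible(rec)
}

#' Notch out 50 Hz powerline interference
#'
#' Applies a Butterworth band-stop filter (default stop band 49-51 Hz,
#' order 4) independently to every channel. With `zero_phase = TRUE`
#' (default) the filter runs forward and backward, doubling the stop-band
#' attenuation and leaving the passband phase untouched.
#'
#' @param rec an `emg_recording`.
#' @param spec a [filter_spec()] of kind `"notch"`.
#' @return A filtered `emg_recording` of identical shape.
#' @examples
#' rec <- simulate_recording(gesture_profiles()[1, ],
#'   sim_config(hold_duration = 0.25), 1, 1)
#' filtered <- notch_filter(rec)
#' @export
notch_filter <- function(rec, spec = filter_spec("notch")) {
  if (spec$kind != "notch") abort("`spec` must have kind 'notch'.")
  check_recording(rec)
  if (rec$fs <= 2 * spec$fc2) abort("sampling rate too low for this notch.")
  co <- design_filter(spec, rec$fs)
  f <- if (spec$zero_phase) {
    function(x) filtfilt_refl(co$b, co$a, x)
  } else {
    function(x) as.numeric(signal::filter(co$b, co$a, x))
  }
  apply_channelwise(rec, f)
}

#' Remove DC offset with a single-pole high-pass
#'
#' First-order recursive high-pass `y[n] = x[n] - x[n-1] + R y[n-1]` with
#' `R = exp(-2 pi dc_cutoff / fs)`, run causally per channel, the software
#' analogue of the DC-blocking stage in the acquisition amplifier. A
#' constant offset decays geometrically with the pole radius.
#'
#' @inheritParams notch_filter
#' @param spec a [filter_spec()] of kind `"dc_block"`.
#' @return An `emg_recording` of identical shape with DC asymptotically
#'   removed.
#' @export
dc_block <- function(rec, spec = filter_spec("dc_block")) {
  if (spec$kind != "dc_block") abort("`spec` must have kind 'dc_block'.")
  check_recording(rec)
  co <- design_filter(spec, rec$fs)
  apply_channelwise(rec, function(x) as.numeric(signal::filter(co$b, co$a, x)))
}

band_limit_filter <- function(rec, spec) {
  if (spec$kind != "band_limit") abort("`spec` must have kind 'band_limit'.")
  check_recording(rec)
  co <- design_filter(spec, rec$fs)
  f <- if (spec$zero_phase) {
    function(x) filtfilt_refl(co$b, co$a, x)
  } else {
    function(x) as.numeric(signal::filter(co$b, co$a, x))
  }
  apply_channelwise(rec, f)
}

#' Apply the standard preprocessing chain
#'
#' DC block followed by the 50 Hz notch (the default order), applied to the
#' whole recording before any windowing. Shape preserving and
#' deterministic.
#'
#' @param rec an `emg_recording`.
#' @param specs non-empty list of [filter_spec()]s, applied in order.
#' @return The filtered `emg_recording`.
#' @examples
#' rec <- simulate_recording(gesture_profiles()[1, ],
#'   sim_config(hold_duration = 0.25), 1, 1)
#' clean <- preprocess_chain(rec)
#' @export
preprocess_chain <- function(rec,
                             specs = list(filter_spec("dc_block"),
                                          filter_spec("notch"))) {
  if (length(specs) == 0) abort("`specs` must be non-empty.")
  check_recording(rec)
  for (spec in specs) {
    rec <- switch(spec$kind,
      dc_block = dc_block(rec, spec),
      notch = notch_filter(rec, spec),
      band_limit = band_limit_filter(rec, spec)
    )
  }
  rec
}

#' Preprocess every recording in a dataset
#'
#' @param data a dataset tibble from [simulate_dataset()] (or any tibble
#'   with a `recording` list column).
#' @inheritParams preprocess_chain
#' @return The tibble with its `recording` column filtered.
#' @export
preprocess_dataset <- function(data,
                               specs = list(filter_spec("dc_block"),
                                            filter_spec("notch"))) {
  data$recording <- purrr::map(data$recording, preprocess_chain, specs = specs)
  data
}

#' Frequency response of a designed filter
#'
#' Evaluates the magnitude response (single forward pass) of the filter a
#' spec designs at sampling rate `fs`, in dB. For zero-phase application
#' the effective attenuation is twice the returned value.
#'
#' @param spec a [filter_spec()].
#' @param fs sampling rate in Hz.
#' @param freq frequencies (Hz) at which to evaluate.
#' @return A tibble with columns `freq` and `mag_db`.
#' @examples
#' filter_response(filter_spec("notch"), 2000, c(10, 50, 100))
#' @export
filter_response <- function(spec, fs, freq) {
  co <- design_filter(spec, fs)
  w <- 2 * pi * freq / fs
  z <- exp(-1i * w)
  num <- vapply(z, function(zz) sum(co$b * zz^(seq_along(co$b) - 1)), complex(1))
  den <- vapply(z, function(zz) sum(co$a * zz^(seq_along(co$a) - 1)), complex(1))
  tibble(freq = freq, mag_db = 20 * log10(Mod(num / den)))
}
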