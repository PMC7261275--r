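#' Alarm-tone frequencies of electrosurgical generators
#'
#' Regulatory activation/alarm tones audible in operating-room recordings:
#' pure sines at 2020 and 3035 Hz in cutting mode and at 1380 and 2270 Hz in
#' coagulation mode. These are the default targets of [notch_spec()] and the
#' tones injected by the synthetic generator.
#'
#' @format Named list with numeric vectors `cut` and `coag` (Hz).
#' @export
alarm_tones <- list(cut = c(2020, 3035), coag = c(1380, 2270))

#' Specify a cascade of notch filters
#'
#' One second-order IIR notch per centre frequency, intended to suppress the
#' generator alarm tones before spectral analysis. The default `Q` of 30 is
#' narrow (bandwidth f0/Q, e.g. 67 Hz at 2 kHz) because the tones are pure
#' sines; neighbouring diathermy content is left essentially untouched.
#'
#' @param center_freqs Numeric vector of centre frequencies in Hz.
#' @param quality_factor Dimensionless Q (centre / -3 dB bandwidth).
#' @return An object of class `notch_spec`.
#' @export
notch_spec <- function(center_freqs = unlist(alarm_tones, use.names = FALSE),
                       quality_factor = 30) {
  if (!is.numeric(center_freqs) || length(center_freqs) == 0L ||
      any(center_freqs <= 0))
    ss_abort("center_freqs must be positive", "surgsound_bad_notch")
  if (quality_factor <= 0)
    ss_abort("quality_factor must be positive", "surgsound_bad_notch")
  structure(list(center_freqs = as.numeric(center_freqs),
                 quality_factor = as.numeric(quality_factor)),
            class = "notch_spec")
}

# Biquad designs (audio-EQ cookbook). Returned as list(b, a), a[1] == 1.
biquad_notch <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

biquad_bandpass <- function(f0, fs, Q) {
  # constant 0 dB peak-gain bandpass (resonator)
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(alpha, 0, -alpha)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Suppress narrowband alarm tones
#'
#' Applies the cascade of second-order notch filters described by a
#' [notch_spec()] to a clip. Output length and rate equal the input's.
#'
#' @param clip An [audio_clip()].
#' @param spec A [notch_spec()]. Defaults to the four electrosurgical alarm
#'   tones at Q = 30.
#' @return The filtered [audio_clip()].
#' @export
apply_notch <- function(clip, spec = notch_spec()) {
  stopifnot(inherits(clip, "audio_clip"), inherits(spec, "notch_spec"))
  nyq <- clip$sample_rate / 2
  if (any(spec$center_freqs >= nyq))
    ss_abort("notch centre frequency at or above Nyquist",
             "surgsound_bad_notch")
  x <- clip$samples
  for (f0 in spec$center_freqs) {
    co <- biquad_notch(f0, clip$sample_rate, spec$quality_factor)
    x <- as.numeric(signal::filter(co$b, co$a, x))
  }
  x[x > 1] <- 1; x[x < -1] <- -1
  audio_clip(x, clip$sample_rate, source_id = clip$source_id)
}

#' Cut a clip into overlapping fixed-length analysis windows
#'
#' A rectangular sliding window with hop `window_ms * (1 - overlap_frac)`:
#' segments start at 0, hop, 2*hop, ... and any trailing partial window is
#' discarded, so every segment has exactly `round(window_ms/1000 * rate)`
#' samples — the fixed-size input the image-rendering stage requires.
#'
#' @param clip An [audio_clip()].
#' @param window_ms Window length in milliseconds (typically 300, 500 or
#'   1000).
#' @param overlap_frac Fractional overlap between consecutive windows in
#'   `[0, 1)`; the canonical setting is 0.75.
#' @return A list of `windowed_segment` objects (possibly empty), each with
#'   fields `samples`, `start_ms`, `window_ms`, `parent_id`, `sample_rate`.
#' @export
slide_windows <- function(clip, window_ms, overlap_frac = 0.75) {
  stopifnot(inherits(clip, "audio_clip"))
  if (!is.numeric(window_ms) || window_ms <= 0)
    ss_abort("window_ms must be positive", "surgsound_bad_window")
  if (!is.numeric(overlap_frac) || overlap_frac < 0 || overlap_frac >= 1)
    ss_abort("overlap_frac must lie in [0, 1)", "surgsound_bad_window")

  fs <- clip$sample_rate
  dur <- clip_duration_ms(clip)
  hop_ms <- window_ms * (1 - overlap_frac)
  win_n <- round(window_ms / 1000 * fs)
  if (dur + 1e-9 < window_ms) return(list())
  n_seg <- floor((dur - window_ms) / hop_ms + 1e-9) + 1

  lapply(seq_len(n_seg) - 1, function(k) {
    start_ms <- k * hop_ms
    i0 <- round(start_ms / 1000 * fs)
    structure(list(samples = clip$samples[(i0 + 1):(i0 + win_n)],
                   start_ms = start_ms, window_ms = window_ms,
                   parent_id = clip$source_id, sample_rate = fs),
              class = "windowed_segment")
  })
}
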