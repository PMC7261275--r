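#' Spectrogram front-end configuration
#'
#' Bundles every parameter of the log-mel front end. Defaults follow the
#' canonical electrosurgery configuration: 2048-sample FFT frames hopped by
#' 512 samples (75% frame overlap) at 44.1 kHz, 256 triangular mel bands
#' spanning `f_min`..11025 Hz, rendered as 299 x 299 x 3 images. `f_min` is
#' where the hard low-cut lives: 0 keeps the full band, 2000 drops the
#' environmental-noise-dominated low end.
#'
#' @param n_fft STFT frame length in samples.
#' @param hop STFT hop in samples; must not exceed `n_fft`.
#' @param n_mels Number of mel filterbank bands.
#' @param f_min,f_max Filterbank frequency range in Hz;
#'   `0 <= f_min < f_max <= sample_rate/2`.
#' @param sample_rate Sampling rate in Hz the config applies to.
#' @param image_size Side length in pixels of the rendered auditory image.
#' @param db_floor Decibel floor; power below `10^(db_floor/10)` is clamped.
#' @param window_ms Analysis-window length in milliseconds for clip
#'   segmentation (300, 500 or 1000 in the standard grid).
#' @param overlap Fractional overlap of consecutive analysis windows.
#' @return An object of class `spectrogram_config`.
#' @export
spectrogram_config <- function(n_fft = 2048L, hop = 512L, n_mels = 256L,
                               f_min = 2000, f_max = 11025,
                               sample_rate = 44100, image_size = 299L,
                               db_floor = -80, window_ms = 500,
                               overlap = 0.75) {
  if (f_min < 0 || f_min >= f_max || f_max > sample_rate / 2)
    ss_abort("need 0 <= f_min < f_max <= sample_rate/2",
             "surgsound_bad_config")
  if (hop > n_fft || hop < 1L)
    ss_abort("need 1 <= hop <= n_fft", "surgsound_bad_config")
  if (n_mels < 1L) ss_abort("n_mels must be >= 1", "surgsound_bad_config")
  if (image_size < 32L)
    ss_abort("image_size must be >= 32", "surgsound_bad_config")
  if (window_ms <= 0 || overlap < 0 || overlap >= 1)
    ss_abort("invalid window_ms/overlap", "surgsound_bad_config")
  structure(list(n_fft = as.integer(n_fft), hop = as.integer(hop),
                 n_mels = as.integer(n_mels), f_min = as.numeric(f_min),
                 f_max = as.numeric(f_max),
                 sample_rate = as.numeric(sample_rate),
                 image_size = as.integer(image_size),
                 db_floor = as.numeric(db_floor),
                 window_ms = as.numeric(window_ms),
                 overlap = as.numeric(overlap)),
            class = "spectrogram_config")
}

#' Hann window
#'
#' `w[n] = (1 - cos(2 pi n / (M - 1))) / 2` for `n = 0, ..., M-1`
#' (symmetric form; endpoints are exactly zero). Applied per STFT frame to
#' limit spectral leakage from the frame truncation.
#'
#' @param M Window length in samples, at least 2.
#' @return Numeric vector of `M` weights in `[0, 1]`.
#' @export
hann_window <- function(M) {
  if (!is.numeric(M) || length(M) != 1L || M < 2)
    ss_abort("Hann window needs M >= 2", "surgsound_bad_window")
  n <- seq_len(M) - 1
  0.5 * (1 - cos(2 * pi * n / (M - 1)))
}

#' Short-time Fourier transform
#'
#' Frame `j` (0-based) covers samples `[j*hop, j*hop + n_fft)`; each frame
#' is Hann-weighted and transformed, and the non-negative frequency bins
#' `0..n_fft/2` are retained.
#'
#' @param segment A `windowed_segment` from [slide_windows()], or any
#'   numeric vector of samples.
#' @param config A [spectrogram_config()].
#' @return List with `values` (complex `(n_fft/2+1) x n_frames` matrix),
#'   `magnitude` (its modulus), `freqs_hz` (bin centre frequencies) and
#'   `n_frames`.
#' @export
stft <- function(segment, config = spectrogram_config()) {
  x <- if (inherits(segment, "windowed_segment")) segment$samples
       else as.numeric(segment)
  n_fft <- config$n_fft; hop <- config$hop
  if (length(x) < n_fft)
    ss_abort(sprintf("segment (%d samples) shorter than n_fft (%d)",
                     length(x), n_fft), "surgsound_short_segment")
  n_frames <- (length(x) - n_fft) %/% hop + 1L
  w <- hann_window(n_fft)
  idx <- outer(seq_len(n_fft), (seq_len(n_frames) - 1L) * hop, `+`)
  frames <- matrix(x[idx], nrow = n_fft) * w
  spec <- stats::mvfft(frames)[seq_len(n_fft %/% 2L + 1L), , drop = FALSE]
  list(values = spec, magnitude = Mod(spec),
       freqs_hz = (seq_len(n_fft %/% 2L + 1L) - 1L) *
         config$sample_rate / n_fft,
       n_frames = n_frames)
}

#' Decibel scaling of a magnitude matrix
#'
#' `10 * log10(max(X^2, eps))` with `eps = 10^(db_floor/10)`, so the output
#' never falls below `db_floor` and zeros map to exactly `db_floor`.
#'
#' @param X Non-negative magnitude matrix (or vector).
#' @param db_floor Decibel floor.
#' @return Matrix of the same shape, in dB.
#' @export
power_to_db <- function(X, db_floor = -80) {
  if (any(!is.finite(X)) || any(X < 0))
    ss_abort("magnitudes must be finite and non-negative",
             "surgsound_bad_magnitude")
  10 * log10(pmax(X^2, 10^(db_floor / 10)))
}

#' Mel scale conversions
#'
#' `f_mel = 2595 * log10(1 + f/700)`; the constant is calibrated so that
#' 1000 Hz maps to (almost exactly) 1000 mel. `mel_to_hz()` is the inverse.
#'
#' @param f Frequency in Hz (non-negative).
#' @param m Frequency in mel.
#' @return Converted frequencies.
#' @export
hz_to_mel <- function(f) {
  if (any(f < 0)) ss_abort("frequency must be non-negative",
                           "surgsound_bad_frequency")
  2595 * log10(1 + f / 700)
}

#' @rdname hz_to_mel
#' @export
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank
#'
#' `n_mels` triangular filters with corner points evenly spaced on the mel
#' scale between `f_min` and `f_max`, peak height 1 (no area
#' normalization — the global dB normalization absorbs scale). FFT bins
#' above `f_max` or below `f_min` get zero weight. A filter so narrow that
#' no FFT bin falls strictly inside its support is snapped to the single
#' bin nearest its centre so that every row keeps positive weight.
#'
#' @param config A [spectrogram_config()].
#' @return `n_mels x (n_fft/2+1)` weight matrix with attribute
#'   `centers_hz` (designed filter centre frequencies).
#' @export
mel_filterbank <- function(config = spectrogram_config()) {
  stopifnot(inherits(config, "spectrogram_config"))
  n_bins <- config$n_fft %/% 2L + 1L
  freqs <- (seq_len(n_bins) - 1L) * config$sample_rate / config$n_fft
  in_range <- sum(freqs >= config$f_min & freqs <= config$f_max)
  if (config$n_mels > in_range)
    ss_abort(sprintf(
      "n_mels = %d exceeds the %d FFT bins available in [%g, %g] Hz",
      config$n_mels, in_range, config$f_min, config$f_max),
      "surgsound_filterbank_resolution")

  mels <- seq(hz_to_mel(config$f_min), hz_to_mel(config$f_max),
              length.out = config$n_mels + 2L)
  corners <- mel_to_hz(mels)
  fb <- matrix(0, nrow = config$n_mels, ncol = n_bins)
  for (m in seq_len(config$n_mels)) {
    lo <- corners[m]; ce <- corners[m + 1L]; hi <- corners[m + 2L]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    w <- pmax(0, pmin(up, down))
    if (all(w == 0)) w[which.min(abs(freqs - ce))] <- 1
    fb[m, ] <- w
  }
  structure(fb, centers_hz = corners[2:(config$n_mels + 1L)])
}

#' Log-mel spectrogram of one analysis window
#'
#' Squared STFT magnitudes are pooled by the triangular mel filterbank and
#' mapped to decibels, giving an `n_mels x n_frames` matrix floored at
#' `db_floor`.
#'
#' @param segment A `windowed_segment` (or sample vector).
#' @param config A [spectrogram_config()].
#' @param filterbank Optional precomputed [mel_filterbank()] for `config`
#'   (passing it avoids rebuilding the bank in tight loops).
#' @return Object of class `log_mel_spectrogram`: list with `values`
#'   (dB matrix), `config`, `segment_ref`.
#' @export
log_mel <- function(segment, config = spectrogram_config(),
                    filterbank = NULL) {
  sp <- stft(segment, config)
  if (is.null(filterbank)) filterbank <- mel_filterbank(config)
  pow <- filterbank %*% (sp$magnitude^2)
  vals <- 10 * log10(pmax(pow, 10^(config$db_floor / 10)))
  ref <- if (inherits(segment, "windowed_segment"))
    sprintf("%s@%gms", segment$parent_id, segment$start_ms) else NA_character_
  structure(list(values = vals, config = config, segment_ref = ref),
            class = "log_mel_spectrogram")
}

#' Fit global normalization statistics
#'
#' Scalar mean and population (divide-by-N) standard deviation pooled over
#' every cell of every spectrogram in the collection — one global (mu,
#' sigma) pair, not per-band statistics. Fit these on the training split to
#' avoid leaking test-set statistics into the features.
#'
#' @param spectrograms List of `log_mel_spectrogram` objects (or plain
#'   matrices).
#' @param fitted_on Label recording which split the statistics came from.
#' @return Object of class `normalization_stats` with fields `mean`, `std`,
#'   `fitted_on`.
#' @export
fit_normalization <- function(spectrograms, fitted_on = "train") {
  if (length(spectrograms) == 0L)
    ss_abort("cannot fit normalization on an empty collection",
             "surgsound_empty_collection")
  s <- 0; s2 <- 0; n <- 0
  for (sp in spectrograms) {
    v <- if (inherits(sp, "log_mel_spectrogram")) sp$values else sp
    s <- s + sum(v); s2 <- s2 + sum(v^2); n <- n + length(v)
  }
  mu <- s / n
  var <- max(s2 / n - mu^2, 0)
  if (var <= 0)
    ss_abort("zero variance: all spectrogram cells identical",
             "surgsound_zero_variance")
  structure(list(mean = mu, std = sqrt(var), fitted_on = fitted_on),
            class = "normalization_stats")
}

# Bilinear (align-corners) interpolation matrix mapping n input points to
# m output points; constant fields stay constant, rows sum to 1.
bilinear_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  if (n_in == 1L) { A[, 1L] <- 1; return(A) }
  u <- (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1) + 1
  lo <- pmin(floor(u), n_in - 1)
  fr <- u - lo
  for (i in seq_len(n_out)) {
    A[i, lo[i]] <- 1 - fr[i]
    A[i, lo[i] + 1] <- A[i, lo[i] + 1] + fr[i]
  }
  A
}

#' Render a normalized fixed-size auditory image
#'
#' Normalizes a log-mel spectrogram by global statistics, bilinearly
#' resizes `n_mels x n_frames` to `image_size x image_size`, and replicates
#' the result across 3 identical channels (grayscale replication preserves
#' all information and assumes no colormap). Row 1 of the pixel array is
#' the top of the image; the mel axis is oriented low-frequency-at-bottom.
#'
#' @param spec A `log_mel_spectrogram`.
#' @param stats A [fit_normalization()] result.
#' @param image_size Output side length in pixels; defaults to the config's.
#' @return Object of class `auditory_image`: list with `pixels`
#'   (`image_size x image_size x 3` array) and `segment_ref`.
#' @export
render_image <- function(spec, stats, image_size = spec$config$image_size) {
  stopifnot(inherits(spec, "log_mel_spectrogram"),
            inherits(stats, "normalization_stats"))
  v <- (spec$values - stats$mean) / stats$std
  rows <- bilinear_matrix(image_size, nrow(v))
  cols <- bilinear_matrix(image_size, ncol(v))
  img <- rows %*% v %*% t(cols)
  img <- img[rev(seq_len(image_size)), , drop = FALSE]  # low mel at bottom
  structure(list(pixels = array(img, dim = c(image_size, image_size, 3L)),
                 segment_ref = spec$segment_ref),
            class = "auditory_image")
}
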