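# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures are stored.

make_sine_clip <- function(freq, dur_ms = 1000, fs = 44100, amp = 1,
                           id = "sine") {
  t <- (seq_len(round(dur_ms / 1000 * fs)) - 1) / fs
  audio_clip(amp * sin(2 * pi * freq * t), fs, source_id = id)
}

# O(N^2) per-frame discrete Fourier transform: the independent oracle for
# stft(). Same framing and Hann weighting, but a literal DFT sum.
naive_stft <- function(x, n_fft, hop) {
  n_frames <- (length(x) - n_fft) %/% hop + 1L
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n_fft) - 1) / (n_fft - 1)))
  n_bins <- n_fft %/% 2L + 1L
  out <- matrix(0i, n_bins, n_frames)
  for (j in seq_len(n_frames)) {
    fr <- x[((j - 1L) * hop + 1L):((j - 1L) * hop + n_fft)] * w
    for (k in seq_len(n_bins)) {
      n <- seq_len(n_fft) - 1L
      out[k, j] <- sum(fr * exp(-2i * pi * (k - 1L) * n / n_fft))
    }
  }
  out
}

# Brute-force enumeration of valid sliding-window start offsets.
enumerate_starts <- function(duration_ms, window_ms, overlap_frac) {
  hop <- window_ms * (1 - overlap_frac)
  starts <- numeric(0)
  s <- 0
  while (s + window_ms <= duration_ms + 1e-9) {
    starts <- c(starts, s)
    s <- s + hop
  }
  starts
}

# Minimal stereo 16-bit PCM WAV writer (test-only; the package writes mono).
write_stereo_wav <- function(path, left, right, fs = 44100) {
  stopifnot(length(left) == length(right))
  q <- as.integer(round(rbind(left, right) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(q) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16L), con, size = 4L, endian = "little")
  writeBin(as.integer(1L), con, size = 2L, endian = "little")
  writeBin(as.integer(2L), con, size = 2L, endian = "little")
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs * 4L), con, size = 4L, endian = "little")
  writeBin(as.integer(4L), con, size = 2L, endian = "little")
  writeBin(as.integer(16L), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  writeBin(as.vector(q), con, size = 2L, endian = "little")
  invisible(path)
}

# Power-spectral centroid of a clip within [f_lo, f_hi] (Hz). Defaults to
# the filterbank analysis band, where class textures are designed to live.
spectral_centroid <- function(clip, f_lo = 0, f_hi = 11025) {
  n <- length(clip$samples)
  p <- Mod(stats::fft(clip$samples))[seq_len(n %/% 2)]^2
  freqs <- (seq_len(n %/% 2) - 1) * clip$sample_rate / n
  keep <- freqs >= f_lo & freqs <= f_hi
  sum(freqs[keep] * p[keep]) / sum(p[keep])
}

# Fraction of spectral energy below a cutoff frequency.
band_energy_fraction <- function(clip, f_hi) {
  n <- length(clip$samples)
  p <- Mod(stats::fft(clip$samples))[seq_len(n %/% 2)]^2
  freqs <- (seq_len(n %/% 2) - 1) * clip$sample_rate / n
  sum(p[freqs < f_hi]) / sum(p)
}

local_wav_path <- function() tempfile(fileext = ".wav")
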