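#' Construct an audio clip
#'
#' The canonical in-memory representation of a waveform: a mono vector of
#' samples in `[-1, 1]` together with its sample rate. All ingestion paths
#' (WAV reading, synthesis) produce this object; all analysis stages consume
#' it.
#'
#' @param samples Numeric vector of mono samples. Must be finite with peak
#'   magnitude at most 1.
#' @param sample_rate Sampling rate in Hz. The package canon is 44100 Hz.
#' @param source_id Opaque clip identifier carried through to manifests.
#' @return An object of class `audio_clip` with fields `samples`,
#'   `sample_rate`, `source_id` and accessor [clip_duration_ms()].
#' @export
audio_clip <- function(samples, sample_rate = 44100, source_id = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L)
    ss_abort("audio clip has zero samples", "surgsound_empty_audio")
  if (!all(is.finite(samples)))
    ss_abort("audio samples must all be finite", "surgsound_nonfinite_audio")
  if (max(abs(samples)) > 1 + 1e-9)
    ss_abort("audio peak magnitude exceeds 1.0", "surgsound_clipped_audio")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    ss_abort("sample_rate must be a positive scalar", "surgsound_bad_rate")
  structure(list(samples = samples, sample_rate = as.numeric(sample_rate),
                 source_id = as.character(source_id)),
            class = "audio_clip")
}

#' @rdname audio_clip
#' @param clip An `audio_clip`.
#' @export
clip_duration_ms <- function(clip) {
  1000 * length(clip$samples) / clip$sample_rate
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %s: %.1f ms @ %g Hz (%d samples, peak %.3f)\n",
              x$source_id, clip_duration_ms(x), x$sample_rate,
              length(x$samples), max(abs(x$samples))))
  invisible(x)
}

# ---- RIFF/WAVE PCM ---------------------------------------------------------
# No WAV reader ships with base R; the format is plain RIFF chunks around
# little-endian integer PCM, parsed here directly.

# 4-byte chunk sizes are read as signed 32-bit; WAV payloads here are far
# below 2 GiB so the sign bit is never set.
read_u32 <- function(con) readBin(con, "integer", 1L, size = 4L,
                                  endian = "little")
read_u16 <- function(con) readBin(con, "integer", 1L, size = 2L,
                                  endian = "little", signed = FALSE)

#' Read a PCM WAV file
#'
#' Reads RIFF/WAVE files with integer PCM payloads (8/16/24/32 bit).
#' Multi-channel audio is averaged to mono; integer samples are scaled to
#' `[-1, 1]` by the full-scale value of the bit depth.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_clip()]; `source_id` is the file name without extension.
#' @export
read_wav <- function(path) {
  if (!file.exists(path))
    ss_abort(sprintf("no such file: %s", path), "surgsound_missing_file")
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, "RIFF"))
    ss_abort(sprintf("not a RIFF/WAVE file: %s", path), "surgsound_not_wav")
  read_u32(con)                           # RIFF payload size, unused
  if (!identical(readChar(con, 4L, useBytes = TRUE), "WAVE"))
    ss_abort(sprintf("not a RIFF/WAVE file: %s", path), "surgsound_not_wav")

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- read_u32(con)
    if (identical(id, "fmt ")) {
      fmt <- list(audio_format = read_u16(con), n_channels = read_u16(con),
                  sample_rate = read_u32(con))
      read_u32(con); read_u16(con)        # byte rate, block align
      fmt$bits <- read_u16(con)
      extra <- size - 16L
      if (extra > 0L) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + size %% 2L)  # skip, chunks are word-aligned
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    ss_abort(sprintf("missing fmt/data chunk: %s", path), "surgsound_not_wav")
  if (fmt$audio_format != 1L)
    ss_abort("only integer PCM WAV is supported", "surgsound_not_wav")
  if (length(data_raw) == 0L)
    ss_abort(sprintf("zero-length audio: %s", path), "surgsound_empty_audio")

  bytes <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes
  x <- switch(as.character(fmt$bits),
    "8"  = as.numeric(as.integer(data_raw[seq_len(n_total)])) - 128,
    "16" = as.numeric(readBin(data_raw, "integer", n_total, size = 2L,
                              endian = "little", signed = TRUE)),
    "24" = {
      m <- matrix(as.integer(data_raw[seq_len(3L * n_total)]), nrow = 3L)
      v <- m[1L, ] + 256 * m[2L, ] + 65536 * m[3L, ]
      ifelse(v >= 8388608, v - 16777216, v)
    },
    "32" = as.numeric(readBin(data_raw, "integer", n_total, size = 4L,
                              endian = "little", signed = TRUE)),
    ss_abort(sprintf("unsupported bit depth: %d", fmt$bits),
             "surgsound_not_wav"))
  x <- x / 2^(fmt$bits - 1L)
  if (fmt$n_channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  x[x > 1] <- 1; x[x < -1] <- -1
  audio_clip(x, fmt$sample_rate,
             source_id = tools::file_path_sans_ext(basename(path)))
}

#' Write a PCM WAV file
#'
#' Writes mono integer PCM. Clips whose peak magnitude exceeds 1 are
#' refused rather than silently hard-clipped.
#'
#' @param clip An [audio_clip()].
#' @param path Output path.
#' @param bit_depth PCM depth, 16 (default) or 24 bits.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, bit_depth = 16L) {
  stopifnot(inherits(clip, "audio_clip"))
  if (!bit_depth %in% c(16L, 24L))
    ss_abort("bit_depth must be 16 or 24", "surgsound_bad_depth")
  if (max(abs(clip$samples)) > 1 + 1e-9)
    ss_abort("refusing to write clip with peak > 1 (would hard-clip)",
             "surgsound_clipped_audio")
  full <- 2^(bit_depth - 1L)
  q <- round(clip$samples * full)
  q[q > full - 1] <- full - 1
  q[q < -full] <- -full

  bytes <- bit_depth %/% 8L
  n <- length(q)
  con <- tryCatch(file(path, "wb"),
                  error = function(e)
                    ss_abort(sprintf("cannot open for writing: %s", path),
                             "surgsound_unwritable"))
  on.exit(close(con))
  data_size <- n * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16L), con, size = 4L, endian = "little")
  writeBin(as.integer(1L), con, size = 2L, endian = "little")  # PCM
  writeBin(as.integer(1L), con, size = 2L, endian = "little")  # mono
  writeBin(as.integer(clip$sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(clip$sample_rate * bytes), con, size = 4L,
           endian = "little")
  writeBin(as.integer(bytes), con, size = 2L, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  if (bit_depth == 16L) {
    writeBin(as.integer(q), con, size = 2L, endian = "little")
  } else {
    v <- ifelse(q < 0, q + 16777216, q)
    raw3 <- as.raw(rbind(v %% 256, (v %/% 256) %% 256, v %/% 65536))
    writeBin(raw3, con)
  }
  invisible(path)
}

#' Resample a clip to a new rate
#'
#' Rational resampling in the discrete-Fourier domain: the spectrum is
#' truncated or zero-padded to the output length, which is exact for
#' band-limited content and preserves duration to within one sample period.
#' Used to canonicalize ingested audio to 44.1 kHz.
#'
#' @param clip An [audio_clip()].
#' @param target_rate Target sampling rate in Hz.
#' @return A resampled [audio_clip()] at `target_rate`.
#' @export
resample_clip <- function(clip, target_rate) {
  stopifnot(inherits(clip, "audio_clip"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0)
    ss_abort("target_rate must be a positive scalar", "surgsound_bad_rate")
  if (target_rate == clip$sample_rate) return(clip)

  x <- clip$samples
  n <- length(x)
  m <- max(1L, round(n * target_rate / clip$sample_rate))
  X <- stats::fft(x)
  Y <- complex(m)
  k <- min(n, m)
  hu <- as.integer(ceiling(k / 2) - 1)   # strictly-below-Nyquist positive bins
  Y[1L] <- X[1L]
  if (hu >= 1L) {
    Y[1L + seq_len(hu)] <- X[1L + seq_len(hu)]
    Y[m + 1L - seq_len(hu)] <- X[n + 1L - seq_len(hu)]
  }
  if (k %% 2L == 0L) {
    if (m > n) {
      # upsampling: split the source Nyquist bin symmetrically
      Y[n %/% 2L + 1L] <- X[n %/% 2L + 1L] / 2
      Y[m - n %/% 2L + 1L] <- Conj(X[n %/% 2L + 1L]) / 2
    } else {
      # downsampling: the real part keeps the output signal real
      Y[m %/% 2L + 1L] <- Re(X[m %/% 2L + 1L])
    }
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  y[y > 1] <- 1; y[y < -1] <- -1
  audio_clip(y, target_rate, source_id = clip$source_id)
}
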