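test_that("Hann window closed forms hold", {
  for (M in c(4L, 17L, 64L, 2048L)) {
    w <- hann_window(M)
    expect_equal(w[1], 0)
    expect_equal(w[M], 0)
    if (M %% 2L == 1L) expect_equal(w[(M - 1L) %/% 2L + 1L], 1)
  }
  expect_equal(hann_window(4), c(0, 0.75, 0.75, 0))
  expect_error(hann_window(1), class = "surgsound_bad_window")
})

test_that("stft matches the naive O(N^2) DFT oracle on random signals", {
  set.seed(31)
  cfg <- spectrogram_config(n_fft = 256L, hop = 64L, n_mels = 40L,
                            f_min = 0, f_max = 4000, sample_rate = 8000)
  for (i in 1:8) {
    x <- stats::rnorm(sample(256:1024, 1))
    got <- stft(x, cfg)$values
    want <- naive_stft(x, 256L, 64L)
    expect_lt(max(Mod(got - want)) / max(Mod(want)), 1e-6)
  }
})

test_that("stft of silence is zero and a bin-centred sine peaks at its bin", {
  cfg <- spectrogram_config(n_fft = 1024L, hop = 256L, n_mels = 40L,
                            f_min = 0, f_max = 22050)
  expect_true(all(stft(numeric(2048), cfg)$magnitude == 0))

  k0 <- 32L                                     # bin frequency k0*fs/n_fft
  f0 <- k0 * 44100 / 1024
  x <- sin(2 * pi * f0 * (0:2047) / 44100)
  mag <- stft(x, cfg)$magnitude
  expect_equal(unname(apply(mag, 2L, which.max)), rep(k0 + 1L, ncol(mag)))
  # Hann-windowed exact-bin sine: |X[k0]| = amp * sum(w)/2 up to leakage
  expect_equal(mag[k0 + 1L, 1L], sum(hann_window(1024L)) / 2,
               tolerance = 1e-3)
})

test_that("decibel mapping honours its closed forms and the floor", {
  expect_equal(power_to_db(1), 0)
  expect_equal(power_to_db(10), 20)
  expect_equal(power_to_db(0), -80)
  expect_equal(power_to_db(0, db_floor = -100), -100)
  expect_true(all(power_to_db(matrix(stats::runif(20), 4)) >= -80))
  expect_error(power_to_db(c(1, -2)), class = "surgsound_bad_magnitude")
})

test_that("mel scale conversions hit the calibration points", {
  expect_equal(hz_to_mel(0), 0)
  expect_equal(hz_to_mel(700), 2595 * log10(2))
  expect_lt(abs(hz_to_mel(1000) - 1000), 0.1)
  expect_error(hz_to_mel(-1), class = "surgsound_bad_frequency")
  # strict monotonicity and inverse consistency
  f <- seq(0, 20000, by = 50)
  expect_true(all(diff(hz_to_mel(f)) > 0))
  expect_equal(mel_to_hz(hz_to_mel(f)), f, tolerance = 1e-9)
})

test_that("mel filterbank triangles are contiguous, evenly spaced, in-range", {
  cfg <- spectrogram_config()
  fb <- mel_filterbank(cfg)
  expect_equal(dim(fb), c(256L, 1025L))
  expect_true(all(fb >= 0))
  expect_true(all(rowSums(fb) > 0))
  # single contiguous support region per filter
  for (m in sample(256L, 40L)) {
    on <- which(fb[m, ] > 0)
    expect_equal(on, seq(min(on), max(on)))
  }
  centers <- attr(fb, "centers_hz")
  expect_true(all(diff(centers) > 0))
  gaps <- diff(hz_to_mel(centers))
  expect_lt(max(gaps) - min(gaps), 1e-9)
  # no weight outside [f_min, f_max]
  freqs <- (0:1024) * 44100 / 2048
  expect_true(all(fb[, freqs < cfg$f_min - 22 | freqs > cfg$f_max + 22] == 0))
})

test_that("the 2 kHz low-cut bank rejects a 1 kHz tone", {
  cfg <- spectrogram_config(f_min = 2000)
  fb <- mel_filterbank(cfg)
  spec_at <- function(f0) {
    x <- sin(2 * pi * f0 * (0:22049) / 44100)
    rowSums(fb %*% stft(x, cfg)$magnitude^2)
  }
  expect_lt(sum(spec_at(1000)) / sum(spec_at(5000)), 1e-8)
})

test_that("filterbank resolution errors when n_mels exceeds the FFT bins", {
  expect_error(
    mel_filterbank(spectrogram_config(n_fft = 256L, hop = 64L,
                                      n_mels = 200L, f_min = 2000)),
    class = "surgsound_filterbank_resolution")
})

test_that("log-mel frame count, silence floor and gain offset behave", {
  cfg <- spectrogram_config(f_min = 2000, window_ms = 500)
  clip <- make_sine_clip(3000, 2000, amp = 0.4)
  seg <- slide_windows(clip, 500, 0.75)[[1]]
  lm <- log_mel(seg, cfg)
  expect_equal(dim(lm$values), c(256L, 40L))  # floor((22050-2048)/512)+1

  sil <- slide_windows(audio_clip(numeric(22050), 44100, "s"), 500, 0)[[1]]
  expect_true(all(log_mel(sil, cfg)$values == -80))

  set.seed(77)
  x <- stats::rnorm(22050, sd = 0.1)
  a <- log_mel(x, cfg)$values
  b <- log_mel(2 * x, cfg)$values
  expect_equal(mean(b - a), 20 * log10(2), tolerance = 1e-6)
  expect_lt(max(abs((b - a) - 20 * log10(2))), 1e-6)
})

test_that("scaling a waveform up never lowers log-mel cells above the floor", {
  set.seed(13)
  cfg <- spectrogram_config(f_min = 0)
  x <- stats::rnorm(22050, sd = 0.05)
  a <- log_mel(x, cfg)$values
  b <- log_mel(3 * x, cfg)$values
  expect_true(all(b[a > -80] >= a[a > -80]))
})

test_that("normalization stats match the two-point closed form and identity", {
  mk <- function(v) structure(list(values = matrix(v), config = NULL,
                                   segment_ref = NA),
                              class = "log_mel_spectrogram")
  st <- fit_normalization(list(mk(0), mk(-80)))
  expect_equal(st$mean, -40)
  expect_equal(st$std, 40)  # population (divide-by-N) convention

  set.seed(99)
  specs <- lapply(1:6, function(i) mk(matrix(stats::rnorm(80, -30, 12), 8)))
  st2 <- fit_normalization(specs)
  z <- unlist(lapply(specs, function(s) (s$values - st2$mean) / st2$std))
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z^2) - mean(z)^2), 1, tolerance = 1e-9)

  expect_error(fit_normalization(list()),
               class = "surgsound_empty_collection")
  expect_error(fit_normalization(list(mk(1), mk(1))),
               class = "surgsound_zero_variance")
})

test_that("auditory images have fixed shape, identical channels, no wraparound", {
  cfg <- spectrogram_config(f_min = 0, window_ms = 500, image_size = 64L)
  stats_ <- structure(list(mean = -40, std = 20, fitted_on = "train"),
                      class = "normalization_stats")
  mk <- function(v) structure(list(values = v, config = cfg,
                                   segment_ref = NA),
                              class = "log_mel_spectrogram")

  img <- render_image(mk(matrix(-20, 256, 40)), stats_)
  expect_equal(dim(img$pixels), c(64L, 64L, 3L))
  expect_equal(as.numeric(img$pixels), rep((-20 - -40) / 20, 64 * 64 * 3),
               tolerance = 1e-12)
  expect_identical(img$pixels[, , 1], img$pixels[, , 2])
  expect_identical(img$pixels[, , 1], img$pixels[, , 3])

  # a bright band at high mel index must land near the image TOP
  v <- matrix(-80, 256, 40); v[200:210, ] <- 0
  px <- render_image(mk(v), stats_)$pixels[, , 1]
  band_rows <- which(rowMeans(px) > stats::quantile(rowMeans(px), 0.9))
  expect_equal(band_rows, seq(min(band_rows), max(band_rows)))  # contiguous
  expect_lt(mean(band_rows), 64 * (1 - 200 / 256) + 3)  # near top

  # window length does not change the output shape
  for (frames in c(5L, 40L, 77L)) {
    p <- render_image(mk(matrix(stats::rnorm(256 * frames), 256)), stats_)
    expect_equal(dim(p$pixels), c(64L, 64L, 3L))
  }
})

test_that("the front end is deterministic on identical input", {
  set.seed(41)
  x <- stats::rnorm(22050, sd = 0.2)
  cfg <- spectrogram_config(f_min = 2000)
  expect_identical(log_mel(x, cfg)$values, log_mel(x, cfg)$values)
})
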