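test_that("default profiles cover each scheme with idle as pure floor", {
  p5 <- default_profiles(label_scheme("tissue5"))
  expect_equal(names(p5), c("idle", "fat", "fascia", "liver", "muscle"))
  expect_equal(nrow(p5$idle$peaks), 0L)
  expect_equal(p5$idle$crackle_rate, 0)

  p9 <- default_profiles(label_scheme("tissue_mode9"))
  expect_length(p9, 9L)
  # cut/coag variants share peak centres but differ in rate and first gain
  expect_equal(p9$fat_cut$peaks$center_hz, p9$fat_coag$peaks$center_hz)
  expect_gt(p9$fat_cut$crackle_rate, p9$fat_coag$crackle_rate)
  expect_gt(p9$fat_cut$peaks$gain_db[1], p9$fat_coag$peaks$gain_db[1])
})

test_that("easy tissue textures are >= 500 Hz apart in spectral centroid", {
  scene <- scene_spec(seed = 10L)
  profs <- default_profiles(label_scheme("tissue5"), "easy")
  cents <- vapply(profs[-1], function(p)
    spectral_centroid(synthesize_clip(p, 1500, scene, seed = 3L),
                      f_lo = 2000),
    numeric(1))
  gaps <- abs(outer(cents, cents, `-`))
  expect_gte(min(gaps[upper.tri(gaps)]), 500)
})

test_that("hard textures sit strictly closer together than easy ones", {
  scene <- scene_spec(seed = 10L)
  centroid_spread <- function(diff) {
    profs <- default_profiles(label_scheme("tissue5"), diff)
    cents <- vapply(profs[-1], function(p)
      spectral_centroid(synthesize_clip(p, 1500, scene, seed = 3L),
                        f_lo = 2000),
      numeric(1))
    g <- abs(outer(cents, cents, `-`))
    mean(g[upper.tri(g)])
  }
  expect_lt(centroid_spread("hard"), centroid_spread("easy"))
})

test_that("clip synthesis is bit-deterministic per seed", {
  scene <- scene_spec(seed = 1L)
  prof <- default_profiles(label_scheme("tissue5"))$liver
  a <- synthesize_clip(prof, 1700, scene, mode = "cut", seed = 42L)
  b <- synthesize_clip(prof, 1700, scene, mode = "cut", seed = 42L)
  expect_identical(a$samples, b$samples)
  c2 <- synthesize_clip(prof, 1700, scene, mode = "cut", seed = 43L)
  expect_false(identical(a$samples, c2$samples))
})

test_that("idle clips hold only low-frequency environmental noise", {
  scene <- scene_spec(seed = 2L)
  idle <- default_profiles(label_scheme("tissue5"))$idle
  clip <- synthesize_clip(idle, 2000, scene, mode = "none", seed = 7L)
  expect_gt(band_energy_fraction(clip, 2000), 0.95)
})

test_that("cutting-mode clips carry alarm lines at 2020 and 3035 Hz", {
  scene <- scene_spec(seed = 2L)
  prof <- default_profiles(label_scheme("tissue5"))$fat
  clip <- synthesize_clip(prof, 2000, scene, mode = "cut", seed = 11L)
  n <- length(clip$samples)
  mag <- Mod(stats::fft(clip$samples))[seq_len(n %/% 2)]
  df <- clip$sample_rate / n
  for (f0 in alarm_tones$cut) {
    k <- round(f0 / df) + 1L
    win <- (k - 40L):(k + 40L)
    expect_lte(abs(which.max(mag[win]) + min(win) - 1L - k), 1L)
  }
})

test_that("alarm tones in synthesized audio are notched out by >= 25 dB", {
  scene <- scene_spec(seed = 2L)
  prof <- default_profiles(label_scheme("tissue5"))$fascia
  for (mode in c("cut", "coag")) {
    clip <- synthesize_clip(prof, 1500, scene, mode = mode, seed = 5L)
    filt <- apply_notch(clip, notch_spec())
    n <- length(clip$samples)
    df <- clip$sample_rate / n
    for (f0 in alarm_tones[[mode]]) {
      band <- (round((f0 - 10) / df):round((f0 + 10) / df)) + 1L
      before <- sqrt(sum(Mod(stats::fft(clip$samples))[band]^2))
      after <- sqrt(sum(Mod(stats::fft(filt$samples))[band]^2))
      expect_gte(20 * log10(before / after), 25)
    }
  }
})

test_that("transition clips switch textures exactly at the annotated time", {
  scene <- scene_spec(seed = 3L)
  profs <- default_profiles(label_scheme("tissue5"))
  tr <- synthesize_transition(profs$fat, profs$muscle, 4000, 1500,
                              crossfade_ms = 0, scene = scene, seed = 9L)
  expect_equal(tr$annotation$truth_ms, 1500)
  expect_equal(tr$annotation$class_before, "fat")
  fs <- tr$clip$sample_rate

  # with zero crossfade, band energies flip abruptly across the boundary
  cut_at <- round(1.5 * fs)
  pre <- audio_clip(tr$clip$samples[1:cut_at], fs, "pre")
  post <- audio_clip(tr$clip$samples[(cut_at + 1):(4 * fs)], fs, "post")
  # fat is centred near 3 kHz, muscle near 8 kHz
  expect_gt(spectral_centroid(post, f_lo = 2000),
            spectral_centroid(pre, f_lo = 2000) + 2000)

  expect_error(
    synthesize_transition(profs$fat, profs$muscle, 4000, 200,
                          crossfade_ms = 500, scene = scene, seed = 1L),
    class = "surgsound_bad_transition")
})

test_that("dataset synthesis is balanced, durations on target, reproducible", {
  dir1 <- file.path(tempdir(), "synth_a")
  dir2 <- file.path(tempdir(), "synth_b")
  unlink(c(dir1, dir2), recursive = TRUE)
  scene <- scene_spec(n_clips_per_class = 6L, seed = 123L)
  man1 <- synthesize_dataset(scene, label_scheme("tissue5"), dir1)
  man2 <- synthesize_dataset(scene, label_scheme("tissue5"), dir2)

  expect_equal(nrow(man1), 30L)
  expect_equal(as.integer(table(man1$tissue)), rep(6L, 5))
  # balanced modes within each non-idle tissue
  expect_true(all(table(man1$mode[man1$tissue != "idle"],
                        man1$tissue[man1$tissue != "idle"]) == 3L))
  expect_identical(man1[, -1], man2[, -1])
  for (f in man1$clip_path)
    expect_identical(readBin(file.path(dir1, f), "raw", 5e5),
                     readBin(file.path(dir2, f), "raw", 5e5))

  # manifest round-trips through CSV
  rt <- read_manifest(dir1)
  expect_equal(rt$clip_id, man1$clip_id)

  durs <- vapply(man1$clip_path, function(f)
    clip_duration_ms(read_wav(file.path(dir1, f))), numeric(1))
  expect_true(all(durs >= 1200))
  expect_lt(abs(mean(durs) - 2000), 150)  # 2.58 * 300/sqrt(30) ~ 141
})

test_that("nearest-centroid on mean log-mel vectors separates easy classes", {
  # sanity floor below the full pipeline: class-average log-mel spectra
  # alone must separate the easy-difficulty classes almost perfectly
  dir <- file.path(tempdir(), "synth_floor")
  unlink(dir, recursive = TRUE)
  scene <- scene_spec(n_clips_per_class = 8L, seed = 55L)
  man <- synthesize_dataset(scene, label_scheme("tissue5"), dir)
  cfg <- spectrogram_config(f_min = 2000, window_ms = 500)
  fb <- mel_filterbank(cfg)
  vecs <- t(vapply(seq_len(nrow(man)), function(r) {
    clip <- read_wav(file.path(dir, man$clip_path[r]))
    segs <- slide_windows(clip, 500, 0.75)
    rowMeans(vapply(segs, function(sg) rowMeans(log_mel(sg, cfg, fb)$values),
                    numeric(256)))
  }, numeric(256)))
  labs <- man$tissue
  half <- seq_len(nrow(man)) %% 2 == 1
  cents <- vapply(unique(labs), function(cl)
    colMeans(vecs[half & labs == cl, , drop = FALSE]), numeric(256))
  pred <- colnames(cents)[apply(vecs[!half, ], 1, function(v)
    which.min(colSums((cents - v)^2)))]
  expect_gte(mean(pred == labs[!half]), 0.95)
})
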