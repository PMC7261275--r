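#' Class-conditional sound texture profile
#'
#' Describes the stationary texture of one interaction class: resonant
#' spectral peaks shaping a noise bed, a Poisson rate of broadband crackle
#' transients (the sputtering of tissue vaporization), and an overall
#' level. The generator makes no claim to model the physics of diathermy —
#' it targets the statistical contract the classifier relies on:
#' class-conditional spectral envelopes with controllable separation.
#'
#' @param name Class label.
#' @param peaks Data frame with columns `center_hz`, `bandwidth_hz`,
#'   `gain_db` (one row per resonant peak); may have zero rows (idle).
#' @param crackle_rate Expected crackle transients per second (Poisson).
#' @param crackle_decay_ms Exponential decay constant of each transient.
#' @param base_level_db Texture RMS level in dBFS.
#' @return Object of class `sound_profile`.
#' @export
sound_profile <- function(name, peaks, crackle_rate = 0,
                          crackle_decay_ms = 4, base_level_db = -20) {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) &&
      (any(peaks$center_hz <= 0) || any(peaks$center_hz >= 22050)))
    ss_abort("peak centres must lie in (0, Nyquist)", "surgsound_bad_profile")
  if (crackle_rate < 0)
    ss_abort("crackle_rate must be >= 0", "surgsound_bad_profile")
  structure(list(name = name, peaks = peaks,
                 crackle_rate = as.numeric(crackle_rate),
                 crackle_decay_ms = as.numeric(crackle_decay_ms),
                 base_level_db = as.numeric(base_level_db)),
            class = "sound_profile")
}

#' Scene-level parameters of a synthetic dataset
#'
#' Encodes the recording conditions being emulated: ~2 s clips (truncated
#' normal durations), generator alarm tones as pure sines (2020/3035 Hz in
#' cutting, 1380/2270 Hz in coagulation mode), and a low-frequency
#' environmental noise floor below 2 kHz. The `difficulty` knob scales how
#' far apart the class spectral envelopes sit: `"easy"` is nearly
#' perfectly classifiable by design, `"hard"` is not.
#'
#' @param n_clips_per_class Clips generated per class.
#' @param duration_mean_ms,duration_sd_ms Clip duration distribution
#'   (normal, truncated below at 1.2 x the longest analysis window).
#' @param alarm_level_db Level of each alarm sine, dBFS.
#' @param noise_floor_db RMS level of the environmental noise bed, dBFS.
#' @param difficulty `"easy"` or `"hard"`.
#' @param seed Top-level generation seed.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(n_clips_per_class = 20L, duration_mean_ms = 2000,
                       duration_sd_ms = 300, alarm_level_db = -28,
                       noise_floor_db = -34,
                       difficulty = c("easy", "hard"), seed = 1L) {
  difficulty <- match.arg(difficulty)
  structure(list(n_clips_per_class = as.integer(n_clips_per_class),
                 duration_mean_ms = as.numeric(duration_mean_ms),
                 duration_sd_ms = as.numeric(duration_sd_ms),
                 alarm_level_db = as.numeric(alarm_level_db),
                 noise_floor_db = as.numeric(noise_floor_db),
                 difficulty = difficulty, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Default class sound profiles
#'
#' Five (tissue) or nine (tissue x mode) profiles. `idle` is the noise
#' floor alone: no peaks, no crackles, no alarms. Easy-difficulty tissues
#' have spectral centroids separated by well over 1 kHz and all peaks above
#' the 2 kHz low-cut, so the classes stay separable under the reduced
#' frequency range; hard-difficulty centroids are compressed into a narrow
#' band. Cutting-mode variants of a tissue share its peaks but raise the
#' crackle rate and the first peak's gain.
#'
#' @param scheme A [label_scheme()].
#' @param difficulty `"easy"` or `"hard"`.
#' @return Named list of [sound_profile()]s, one per class of the scheme.
#' @export
default_profiles <- function(scheme, difficulty = c("easy", "hard")) {
  stopifnot(inherits(scheme, "label_scheme"))
  difficulty <- match.arg(difficulty)
  base <- if (difficulty == "easy") {
    list(fat    = list(c(2800, 350, 0), c(3600, 450, -6), rate = 30),
         fascia = list(c(4300, 400, 0), c(5200, 500, -6), rate = 16),
         liver  = list(c(6100, 450, 0), c(7100, 550, -6), rate = 7),
         muscle = list(c(8200, 500, 0), c(9600, 700, -6), rate = 45))
  } else {
    list(fat    = list(c(4000, 500, 0), c(4500, 600, -3), rate = 20),
         fascia = list(c(4350, 500, 0), c(4850, 600, -3), rate = 16),
         liver  = list(c(4700, 500, 0), c(5200, 600, -3), rate = 12),
         muscle = list(c(5050, 500, 0), c(5550, 600, -3), rate = 24))
  }
  mk <- function(nm, spec, mode = NULL) {
    pk <- do.call(rbind, lapply(spec[c(1, 2)], function(p)
      data.frame(center_hz = p[1], bandwidth_hz = p[2], gain_db = p[3])))
    rate <- spec$rate
    if (identical(mode, "cut")) {
      pk$gain_db[1] <- pk$gain_db[1] + 6
      rate <- rate * 1.6
    }
    sound_profile(if (is.null(mode)) nm else paste(nm, mode, sep = "_"),
                  pk, crackle_rate = rate)
  }
  profs <- list(idle = sound_profile("idle",
                                     peaks = data.frame(center_hz = numeric(),
                                                        bandwidth_hz = numeric(),
                                                        gain_db = numeric()),
                                     crackle_rate = 0))
  if (scheme$mode == "tissue5") {
    for (nm in names(base)) profs[[nm]] <- mk(nm, base[[nm]])
  } else {
    for (nm in names(base))
      for (mode in c("cut", "coag"))
        profs[[paste(nm, mode, sep = "_")]] <- mk(nm, base[[nm]], mode)
  }
  profs[scheme$classes]
}

# Stationary texture of a profile: white noise through each resonant peak
# (constant-peak-gain bandpass), summed with per-peak gains, scaled to the
# profile's RMS level. Returns silence for a peakless profile.
render_texture <- function(profile, n, fs) {
  if (nrow(profile$peaks) == 0L) return(numeric(n))
  noise <- stats::rnorm(n)
  x <- numeric(n)
  for (i in seq_len(nrow(profile$peaks))) {
    p <- profile$peaks[i, ]
    co <- biquad_bandpass(p$center_hz, fs, p$center_hz / p$bandwidth_hz)
    x <- x + db_to_amp(p$gain_db) *
      as.numeric(signal::filter(co$b, co$a, noise))
  }
  x / max(rms(x), 1e-12) * db_to_amp(profile$base_level_db)
}

# Poisson crackle transients: short broadband bursts with exponential decay.
render_crackles <- function(profile, n, fs, level_db) {
  if (profile$crackle_rate <= 0) return(numeric(n))
  x <- numeric(n)
  dur_s <- n / fs
  n_ev <- stats::rpois(1L, profile$crackle_rate * dur_s)
  if (n_ev == 0L) return(x)
  len <- max(8L, round(3 * profile$crackle_decay_ms / 1000 * fs))
  env <- exp(-(seq_len(len) - 1) / (profile$crackle_decay_ms / 1000 * fs))
  amp <- db_to_amp(level_db)
  for (t0 in sample.int(max(n - len, 1L), n_ev, replace = TRUE)) {
    x[t0:(t0 + len - 1L)] <- x[t0:(t0 + len - 1L)] +
      amp * stats::rnorm(len) * env
  }
  x
}

# Low-frequency environmental bed: white noise through a one-pole lowpass
# (1/f-like tilt) then band-limited below 2 kHz, at the scene noise floor.
render_environment <- function(n, fs, level_db) {
  noise <- stats::rnorm(n)
  tilt <- as.numeric(signal::filter(c(1), c(1, -0.98), noise))
  bw <- signal::butter(4, 2000 / (fs / 2), type = "low")
  x <- as.numeric(signal::filter(bw$b, bw$a, tilt))
  x / max(rms(x), 1e-12) * db_to_amp(level_db)
}

alarm_signal <- function(mode, n, fs, level_db) {
  if (!mode %in% c("cut", "coag")) return(numeric(n))
  t <- (seq_len(n) - 1) / fs
  a <- db_to_amp(level_db)
  rowSums(vapply(alarm_tones[[mode]],
                 function(f) a * sin(2 * pi * f * t), numeric(n)))
}

#' Synthesize one labelled clip
#'
#' Band-shaped noise through the profile's resonant peaks, plus Poisson
#' crackle transients, mode-matched alarm sines and the low-frequency
#' environmental bed. Deterministic for a given seed; peak-normalized only
#' if the mix exceeds full scale.
#'
#' @param profile A [sound_profile()].
#' @param duration_ms Clip length in milliseconds.
#' @param scene A [scene_spec()] (levels for alarms/noise floor).
#' @param mode `"cut"`, `"coag"` or `"none"` — selects the alarm tones.
#' @param seed Integer seed.
#' @param sample_rate Sampling rate in Hz.
#' @param source_id Clip identifier.
#' @return An [audio_clip()].
#' @export
synthesize_clip <- function(profile, duration_ms, scene = scene_spec(),
                            mode = "none", seed = 1L, sample_rate = 44100,
                            source_id = profile$name) {
  if (duration_ms <= 0)
    ss_abort("duration must be positive", "surgsound_bad_duration")
  n <- round(duration_ms / 1000 * sample_rate)
  x <- with_local_seed(seed, {
    render_texture(profile, n, sample_rate) +
      render_crackles(profile, n, sample_rate,
                      profile$base_level_db + 2) +
      render_environment(n, sample_rate, scene$noise_floor_db) +
      alarm_signal(mode, n, sample_rate, scene$alarm_level_db)
  })
  pk <- max(abs(x))
  if (pk > 1) x <- x / (pk * 1.001)
  audio_clip(x, sample_rate, source_id = source_id)
}

#' Synthesize a two-texture transition clip
#'
#' Texture A up to `truth_ms`, texture B after it, blended by a linear
#' crossfade of width `crossfade_ms` centred at the transition; alarms and
#' environment span the whole clip. The annotation records the ground
#' truth for transition-localization experiments.
#'
#' @param profile_a,profile_b [sound_profile()]s before/after transition.
#' @param duration_ms Total clip length.
#' @param truth_ms Transition time; `crossfade_ms < min(truth_ms,
#'   duration_ms - truth_ms)` is required.
#' @param crossfade_ms Width of the linear blend.
#' @param scene A [scene_spec()].
#' @param mode Alarm mode for the whole clip.
#' @param seed Integer seed.
#' @param sample_rate Sampling rate in Hz.
#' @param source_id Clip identifier.
#' @return List with `clip` ([audio_clip()]) and `annotation` (list with
#'   `clip_id`, `class_before`, `class_after`, `truth_ms`, `crossfade_ms`).
#' @export
synthesize_transition <- function(profile_a, profile_b, duration_ms,
                                  truth_ms, crossfade_ms = 50,
                                  scene = scene_spec(), mode = "coag",
                                  seed = 1L, sample_rate = 44100,
                                  source_id = NULL) {
  if (truth_ms <= 0 || truth_ms >= duration_ms)
    ss_abort("truth_ms must lie strictly inside the clip",
             "surgsound_bad_transition")
  if (crossfade_ms >= min(truth_ms, duration_ms - truth_ms))
    ss_abort("crossfade wider than the shorter side of the transition",
             "surgsound_bad_transition")
  if (is.null(source_id))
    source_id <- sprintf("trans_%s_%s_s%d", profile_a$name, profile_b$name,
                         as.integer(seed))
  n <- round(duration_ms / 1000 * sample_rate)
  x <- with_local_seed(seed, {
    a <- render_texture(profile_a, n, sample_rate) +
      render_crackles(profile_a, n, sample_rate, profile_a$base_level_db + 2)
    b <- render_texture(profile_b, n, sample_rate) +
      render_crackles(profile_b, n, sample_rate, profile_b$base_level_db + 2)
    t_ms <- (seq_len(n) - 1) / sample_rate * 1000
    w <- if (crossfade_ms > 0)
      pmin(1, pmax(0, (t_ms - (truth_ms - crossfade_ms / 2)) / crossfade_ms))
    else as.numeric(t_ms >= truth_ms)
    (1 - w) * a + w * b +
      render_environment(n, sample_rate, scene$noise_floor_db) +
      alarm_signal(mode, n, sample_rate, scene$alarm_level_db)
  })
  pk <- max(abs(x))
  if (pk > 1) x <- x / (pk * 1.001)
  list(clip = audio_clip(x, sample_rate, source_id = source_id),
       annotation = list(clip_id = source_id,
                         class_before = profile_a$name,
                         class_after = profile_b$name,
                         truth_ms = truth_ms, crossfade_ms = crossfade_ms))
}

#' Synthesize a labelled dataset of WAV clips
#'
#' Generates `n_clips_per_class` clips per class of the scheme with
#' durations drawn from a truncated normal, balanced operation modes
#' within each tissue, writes 16-bit mono WAV files plus a manifest CSV
#' (`clip_path, clip_id, tissue, mode, split, transition_ms`), and returns
#' the manifest. Fully reproducible from `scene$seed`.
#'
#' @param scene A [scene_spec()].
#' @param scheme A [label_scheme()]. Under `tissue5` each tissue's clips
#'   alternate cutting/coagulation mode (idle clips have none); under
#'   `tissue_mode9` the mode is part of the class.
#' @param out_dir Output directory (created if missing).
#' @param max_window_ms Longest analysis window the clips must
#'   accommodate; durations are truncated below at 1.2 x this value.
#' @return The manifest as a data frame (invisible column `clip_path` is
#'   relative to `out_dir`).
#' @export
synthesize_dataset <- function(scene, scheme = label_scheme("tissue5"),
                               out_dir, max_window_ms = 1000) {
  stopifnot(inherits(scene, "scene_spec"), inherits(scheme, "label_scheme"))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    ss_abort(sprintf("cannot create output directory: %s", out_dir),
             "surgsound_unwritable")
  profiles <- default_profiles(scheme, scene$difficulty)
  rows <- list()
  k <- 0L
  for (cl in scheme$classes) {
    tissue <- sub("_(cut|coag)$", "", cl)
    cl_mode <- if (grepl("_cut$", cl)) "cut"
               else if (grepl("_coag$", cl)) "coag" else NA_character_
    for (i in seq_len(scene$n_clips_per_class)) {
      k <- k + 1L
      clip_seed <- derive_seed(scene$seed, sprintf("clip_%s_%d", cl, i))
      dur <- with_local_seed(derive_seed(clip_seed, "dur"),
        max(1.2 * max_window_ms,
            stats::rnorm(1L, scene$duration_mean_ms, scene$duration_sd_ms)))
      mode <- if (tissue == "idle") "none"
              else if (!is.na(cl_mode)) cl_mode
              else c("cut", "coag")[(i - 1L) %% 2L + 1L]
      clip_id <- sprintf("clip_%04d_%s", k, cl)
      clip <- synthesize_clip(profiles[[cl]], dur, scene, mode = mode,
                              seed = clip_seed, source_id = clip_id)
      path <- file.path(out_dir, paste0(clip_id, ".wav"))
      write_wav(clip, path)
      rows[[k]] <- data.frame(clip_path = basename(path), clip_id = clip_id,
                              tissue = tissue, mode = mode,
                              split = NA_character_,
                              transition_ms = NA_real_)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
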