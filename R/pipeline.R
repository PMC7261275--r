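#' Compute features for every analysis window of a dataset
#'
#' Reads each manifest clip, cuts it into sliding analysis windows, computes
#' log-mel spectrograms, fits the global normalization on the training
#' split (or on everything, if requested), renders auditory images and
#' extracts backbone features.
#'
#' @param manifest Data frame with `clip_path`, `clip_id`, `tissue`,
#'   `mode`, `split` columns (see [synthesize_dataset()] and
#'   [split_dataset()]).
#' @param dir Directory the `clip_path`s are relative to.
#' @param config A [spectrogram_config()]; its `window_ms`/`overlap`
#'   control segmentation.
#' @param scheme A [label_scheme()].
#' @param backbone A `conv_backbone`; defaults to [random_backbone()]
#'   matched to `config$image_size`.
#' @param norm_stats Optional precomputed [fit_normalization()] result
#'   (e.g. when featurizing new data for an existing model).
#' @param norm_on `"train"` (default; leakage-safe) or `"all"`, which
#'   pools the statistics over the entire dataset.
#' @param notch Optional [notch_spec()] applied to each clip before
#'   segmentation; `NULL` (default) disables notch filtering, which in
#'   practice does not improve classification.
#' @return List with `features` (`n x d` matrix), `meta` (data frame:
#'   `clip_id`, `class`, `split`, `start_ms`), `norm_stats`, `backbone`,
#'   `config`, `scheme`.
#' @export
featurize_dataset <- function(manifest, dir, config = spectrogram_config(),
                              scheme = label_scheme("tissue5"),
                              backbone = NULL, norm_stats = NULL,
                              norm_on = c("train", "all"), notch = NULL) {
  norm_on <- match.arg(norm_on)
  if (is.null(backbone))
    backbone <- random_backbone(seed = 1L, input_size = config$image_size)
  cls <- scheme_labels(manifest, scheme)
  fb <- mel_filterbank(config)

  specs <- list(); meta <- list(); k <- 0L
  for (r in seq_len(nrow(manifest))) {
    clip <- read_wav(file.path(dir, manifest$clip_path[r]))
    if (clip$sample_rate != config$sample_rate)
      clip <- resample_clip(clip, config$sample_rate)
    if (!is.null(notch)) clip <- apply_notch(clip, notch)
    for (sg in slide_windows(clip, config$window_ms, config$overlap)) {
      k <- k + 1L
      specs[[k]] <- log_mel(sg, config, fb)
      meta[[k]] <- data.frame(clip_id = manifest$clip_id[r],
                              class = cls[r],
                              split = manifest$split[r],
                              start_ms = sg$start_ms)
    }
  }
  meta <- do.call(rbind, meta)
  if (is.null(norm_stats)) {
    fit_idx <- if (norm_on == "train" && any(meta$split == "train",
                                             na.rm = TRUE))
      which(meta$split == "train") else seq_len(k)
    norm_stats <- fit_normalization(specs[fit_idx],
                                    fitted_on = norm_on)
  }
  features <- t(vapply(specs, function(sp)
    extract_features(render_image(sp, norm_stats), backbone),
    numeric(backbone$n_features)))
  list(features = features, meta = meta, norm_stats = norm_stats,
       backbone = backbone, config = config, scheme = scheme)
}

#' Run one end-to-end experiment
#'
#' Splits the manifest at clip level, featurizes, trains the softmax head,
#' and evaluates on the held-out test windows. The returned model is
#' self-describing: it carries the spectrogram configuration, the
#' normalization statistics and the backbone, so it can classify raw audio
#' directly (see [localize_transition()]).
#'
#' @param manifest Dataset manifest (see [synthesize_dataset()]).
#' @param dir Directory containing the WAV files.
#' @param config A [spectrogram_config()].
#' @param scheme A [label_scheme()].
#' @param tconfig A [train_config()].
#' @param seed Top-level seed; the split, backbone and training streams
#'   are derived from it.
#' @param fractions Train/val/test fractions.
#' @param norm_on `"train"` or `"all"` (see [featurize_dataset()]).
#' @param notch Optional [notch_spec()] applied before segmentation.
#' @param shuffle_labels If `TRUE`, window labels are randomly permuted
#'   before training — a leakage control whose test accuracy must sit at
#'   chance.
#' @return List with `model` (`head_model`), `report` (test-set
#'   [metrics()]), `confusion`, `test_accuracy`, `meta`.
#' @export
run_experiment <- function(manifest, dir, config = spectrogram_config(),
                           scheme = label_scheme("tissue5"),
                           tconfig = NULL, seed = 1L,
                           fractions = c(0.8, 0.1, 0.1),
                           norm_on = c("train", "all"), notch = NULL,
                           shuffle_labels = FALSE) {
  norm_on <- match.arg(norm_on)
  if (is.null(tconfig)) tconfig <- train_config(seed = derive_seed(seed,
                                                                   "train"))
  manifest <- split_dataset(manifest, fractions, seed = seed,
                            scheme = scheme)
  backbone <- random_backbone(seed = derive_seed(seed, "backbone"),
                              input_size = config$image_size)
  fz <- featurize_dataset(manifest, dir, config, scheme, backbone,
                          norm_on = norm_on, notch = notch)
  labels <- fz$meta$class
  if (shuffle_labels)
    labels <- with_local_seed(derive_seed(seed, "shuffle"), sample(labels))

  model <- train_head(fz$features, labels, fz$meta$split, scheme, tconfig)
  model$spectrogram_config <- config
  model$norm_stats <- fz$norm_stats
  model$backbone <- backbone

  te <- which(fz$meta$split == "test")
  pred <- predict(model, fz$features[te, , drop = FALSE])$labels
  cm <- confusion(labels[te], pred, scheme)
  rep <- metrics(cm)
  list(model = model, report = rep, confusion = cm,
       test_accuracy = rep$top1_accuracy, meta = fz$meta)
}

#' Sweep the spectrogram configuration grid
#'
#' Runs the full pipeline for every combination of analysis-window length
#' and filterbank low-cut and tabulates held-out test accuracy — the
#' standard 3 x 2 comparison of front-end configurations.
#'
#' @param manifest Dataset manifest.
#' @param dir Directory containing the WAV files.
#' @param window_ms_values Analysis-window lengths to sweep (ms).
#' @param f_min_values Filterbank low-cut values to sweep (Hz).
#' @param scheme A [label_scheme()].
#' @param seed Top-level seed (shared across cells so the split is
#'   comparable).
#' @param ... Passed to [run_experiment()].
#' @return Numeric matrix `length(f_min_values) x
#'   length(window_ms_values)` of test accuracies, dimnames `f_min` and
#'   `window_ms`.
#' @export
run_grid <- function(manifest, dir, window_ms_values = c(300, 500, 1000),
                     f_min_values = c(0, 2000),
                     scheme = label_scheme("tissue5"), seed = 1L, ...) {
  acc <- matrix(NA_real_, length(f_min_values), length(window_ms_values),
                dimnames = list(f_min = f_min_values,
                                window_ms = window_ms_values))
  for (i in seq_along(f_min_values)) {
    for (j in seq_along(window_ms_values)) {
      cfg <- spectrogram_config(f_min = f_min_values[i],
                                window_ms = window_ms_values[j])
      res <- run_experiment(manifest, dir, cfg, scheme, seed = seed, ...)
      acc[i, j] <- res$test_accuracy
    }
  }
  acc
}
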