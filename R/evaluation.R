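#' Confusion matrix
#'
#' Rows index the ground truth, columns the prediction, in the class order
#' of the scheme.
#'
#' @param y_true,y_pred Equal-length label vectors drawn from the scheme's
#'   classes.
#' @param scheme A [label_scheme()].
#' @return Object of class `confusion_matrix`: integer `M x M` matrix
#'   `counts` plus the scheme.
#' @export
confusion <- function(y_true, y_pred, scheme) {
  stopifnot(inherits(scheme, "label_scheme"))
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    ss_abort("label sequences differ in length", "surgsound_dim_mismatch")
  bad <- setdiff(unique(c(y_true, y_pred)), scheme$classes)
  if (length(bad))
    ss_abort(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")),
             "surgsound_unknown_label")
  f <- factor(y_true, levels = scheme$classes)
  g <- factor(y_pred, levels = scheme$classes)
  counts <- unclass(table(truth = f, prediction = g))
  structure(list(counts = counts, label_scheme = scheme),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %s, %d samples\n", x$label_scheme$mode,
              sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and their harmonic
#' mean F1; top-1 accuracy `trace/total`; macro averages are unweighted
#' class means. A class with a zero denominator (never predicted / never
#' true) scores 0 for the affected metric, with a warning.
#'
#' @param cm A [confusion()] result.
#' @return Object of class `metrics_report`: named per-class vectors
#'   `precision`, `recall`, `f1` and scalars `macro_precision`,
#'   `macro_recall`, `macro_f1`, `top1_accuracy`, `n`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  C <- cm$counts
  total <- sum(C)
  if (total == 0L)
    ss_abort("empty confusion matrix", "surgsound_empty_collection")
  tp <- diag(C)
  pred_tot <- colSums(C)
  true_tot <- rowSums(C)
  if (any(pred_tot == 0) || any(true_tot == 0))
    ss_warn(sprintf(
      "class(es) with zero denominator score 0: %s",
      paste(unique(cm$label_scheme$classes[pred_tot == 0 | true_tot == 0]),
            collapse = ", ")), "surgsound_degenerate_class")
  precision <- ifelse(pred_tot > 0, tp / pred_tot, 0)
  recall <- ifelse(true_tot > 0, tp / true_tot, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  names(precision) <- names(recall) <- names(f1) <- cm$label_scheme$classes
  structure(list(precision = precision, recall = recall, f1 = f1,
                 macro_precision = mean(precision),
                 macro_recall = mean(recall), macro_f1 = mean(f1),
                 top1_accuracy = sum(tp) / total, n = total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> n = %d | accuracy %.4f | macro ",
                     "precision %.4f recall %.4f F1 %.4f\n"),
              x$n, x$top1_accuracy, x$macro_precision, x$macro_recall,
              x$macro_f1))
  print(round(rbind(precision = x$precision, recall = x$recall, f1 = x$f1),
              4))
  invisible(x)
}

#' Collapse a 9-class confusion matrix over operation modes
#'
#' Sums cutting and coagulation rows/columns of each tissue, yielding the
#' 5-class matrix the same predictions would produce after mapping labels
#' to tissues.
#'
#' @param cm A `confusion_matrix` under the `tissue_mode9` scheme.
#' @return A `confusion_matrix` under `tissue5`.
#' @export
collapse_modes <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$label_scheme$mode != "tissue_mode9")
    ss_abort("collapse_modes needs a tissue_mode9 matrix",
             "surgsound_bad_config")
  s5 <- label_scheme("tissue5")
  tissue_of <- sub("_(cut|coag)$", "", cm$label_scheme$classes)
  A <- outer(s5$classes, tissue_of, `==`) * 1  # 5 x 9 aggregation
  counts <- A %*% cm$counts %*% t(A)
  dimnames(counts) <- list(truth = s5$classes, prediction = s5$classes)
  structure(list(counts = counts, label_scheme = s5),
            class = "confusion_matrix")
}

# Sliding-window majority filter of odd width; ends use the shrunken
# window. Ties keep the original label.
majority_filter <- function(labels, width = 3L) {
  n <- length(labels)
  half <- width %/% 2L
  out <- labels
  for (i in seq_len(n)) {
    w <- labels[max(1L, i - half):min(n, i + half)]
    tab <- table(w)
    top <- names(tab)[tab == max(tab)]
    out[i] <- if (labels[i] %in% top) labels[i] else top[1L]
  }
  out
}

#' Locate a tissue transition in an audio stream
#'
#' Classifies every sliding analysis window of the stream with a trained
#' pipeline model, smooths the label sequence with a width-3 majority
#' filter to kill single-window flickers, and places the estimated
#' transition at the midpoint between the temporal centres of the last
#' window of the first stable label run and the first window of the next
#' run. Window centres (start + window/2) are used because a window's
#' label describes its whole span; midpointing the starts instead would
#' bias every estimate early by half a window.
#'
#' @param stream An [audio_clip()] longer than one analysis window.
#' @param model A pipeline-trained `head_model` carrying
#'   `spectrogram_config`, `norm_stats` and `backbone` (see
#'   [run_experiment()]).
#' @param truth_ms Optional annotated transition time; if given, the
#'   absolute offset is filled in.
#' @return Object of class `transition_estimate`: list with `clip_id`,
#'   `estimated_ms` (NA when no transition is detected), `detected`,
#'   `truth_ms`, `offset_ms`, `labels` (smoothed per-window labels) and
#'   `start_ms`.
#' @export
localize_transition <- function(stream, model, truth_ms = NA_real_) {
  stopifnot(inherits(stream, "audio_clip"), inherits(model, "head_model"))
  cfg <- model$spectrogram_config
  if (is.null(cfg) || is.null(model$backbone) || is.null(model$norm_stats))
    ss_abort("model lacks front-end state; train it via run_experiment()",
             "surgsound_bad_checkpoint")
  segs <- slide_windows(stream, cfg$window_ms, cfg$overlap)
  if (length(segs) < 2L)
    ss_abort("stream shorter than two analysis windows",
             "surgsound_short_segment")
  fb <- mel_filterbank(cfg)
  feats <- t(vapply(segs, function(sg)
    extract_features(render_image(log_mel(sg, cfg, fb), model$norm_stats),
                     model$backbone),
    numeric(model$backbone$n_features)))
  raw <- predict(model, feats)$labels
  lab <- majority_filter(raw, 3L)
  start_ms <- vapply(segs, `[[`, numeric(1), "start_ms")

  change <- which(lab[-1L] != lab[-length(lab)])
  est <- NA_real_
  detected <- length(change) > 0L
  if (detected) {
    i <- change[1L]
    centre <- start_ms + cfg$window_ms / 2
    est <- (centre[i] + centre[i + 1L]) / 2
  }
  structure(list(clip_id = stream$source_id, estimated_ms = est,
                 detected = detected, truth_ms = truth_ms,
                 offset_ms = if (detected && !is.na(truth_ms))
                   abs(est - truth_ms) else NA_real_,
                 labels = lab, start_ms = start_ms),
            class = "transition_estimate")
}

#' Offset statistics over transition estimates
#'
#' @param estimates List of `transition_estimate`s (or a numeric vector of
#'   offsets in ms). Estimates without a detected transition or without
#'   ground truth are dropped with a warning.
#' @return List with `mean_ms`, `median_ms`, `n`.
#' @export
offset_stats <- function(estimates) {
  offs <- if (is.numeric(estimates)) estimates
  else vapply(estimates, function(e) e$offset_ms, numeric(1))
  keep <- is.finite(offs)
  if (!all(keep))
    ss_warn(sprintf("%d estimate(s) without detected transition dropped",
                    sum(!keep)), "surgsound_missing_transition")
  offs <- offs[keep]
  if (length(offs) == 0L)
    ss_abort("no usable transition estimates", "surgsound_empty_collection")
  list(mean_ms = mean(offs), median_ms = stats::median(offs),
       n = length(offs))
}
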