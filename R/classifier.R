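#' Label schemes for instrument-tissue interaction
#'
#' Two class layouts are supported: `tissue5` — idle plus the four tissue
#' types (fat, fascia, liver, muscle) — and `tissue_mode9`, which splits
#' each tissue by electrosurgical operation mode (cutting/coagulation),
#' giving idle + 4 x 2 = 9 classes.
#'
#' @param mode `"tissue5"` or `"tissue_mode9"`.
#' @return Object of class `label_scheme` with fields `mode` and `classes`
#'   (ordered class names).
#' @export
label_scheme <- function(mode = c("tissue5", "tissue_mode9")) {
  mode <- match.arg(mode)
  tissues <- c("fat", "fascia", "liver", "muscle")
  classes <- switch(mode,
    tissue5 = c("idle", tissues),
    tissue_mode9 = c("idle",
                     as.vector(t(outer(tissues, c("cut", "coag"),
                                       paste, sep = "_")))))
  structure(list(mode = mode, classes = classes), class = "label_scheme")
}

#' Map manifest rows to scheme labels
#'
#' Derives the class label of each clip from its `tissue` and `mode`
#' manifest columns under a given scheme (`idle` stays `idle`; under
#' `tissue_mode9` other clips become `tissue_mode`).
#'
#' @param manifest Data frame with columns `tissue` and `mode`.
#' @param scheme A [label_scheme()].
#' @return Character vector of class labels.
#' @export
scheme_labels <- function(manifest, scheme) {
  stopifnot(inherits(scheme, "label_scheme"))
  lab <- if (scheme$mode == "tissue5") manifest$tissue
         else ifelse(manifest$tissue == "idle", "idle",
                     paste(manifest$tissue, manifest$mode, sep = "_"))
  bad <- setdiff(unique(lab), scheme$classes)
  if (length(bad))
    ss_abort(sprintf("labels outside scheme '%s': %s", scheme$mode,
                     paste(bad, collapse = ", ")),
             "surgsound_unknown_label")
  lab
}

#' Frozen random-weight convolutional feature extractor
#'
#' The backbone contract is simply image -> fixed-length vector. The
#' default backbone is a seeded, frozen, random-weight convolutional
#' extractor: the input image is bilinearly reduced to 64 x 64, decomposed
#' into 5 x 5 patches at stride 2, projected through 32 random Gaussian
#' filters with ReLU, and average-pooled over an 8 x 8 spatial grid —
#' yielding 8 x 8 x 32 = 2048 features. Random convolutional features are a
#' recognised baseline for auditory images: untrained filter banks already
#' expose the band-position structure a linear readout needs. The extractor
#' is deterministic given its seed, needs no download, and is swappable for
#' any pretrained CNN exposing the same contract.
#'
#' @param seed Integer seed generating the frozen filter weights.
#' @param input_size Expected side length of incoming images (pixels).
#' @param grid_size Internal working resolution (pixels per side).
#' @param patch Patch side length in pixels.
#' @param stride Patch stride in pixels.
#' @param n_filters Number of random filters.
#' @param pool Pooling grid side length; features = pool^2 * n_filters.
#' @return Object of class `conv_backbone` with an `extractor_id`.
#' @export
random_backbone <- function(seed = 1L, input_size = 299L, grid_size = 64L,
                            patch = 5L, stride = 2L, n_filters = 32L,
                            pool = 8L) {
  n_pos <- (grid_size - patch) %/% stride + 1L
  W <- with_local_seed(derive_seed(seed, "backbone"),
                       matrix(stats::rnorm(patch^2 * n_filters, sd = 1 / patch),
                              nrow = patch^2))
  # im2col index matrix: rows = patch pixels, cols = patch positions
  offs <- as.vector(outer(seq_len(patch),
                          (seq_len(patch) - 1L) * grid_size, `+`))
  starts <- as.vector(outer((seq_len(n_pos) - 1L) * stride,
                            (seq_len(n_pos) - 1L) * stride * grid_size, `+`))
  idx <- outer(offs, starts, `+`)
  cell <- function(p) pmin(floor((p - 1L) * pool / n_pos) + 1L, pool)
  pos_cell <- as.vector(outer(cell(seq_len(n_pos)),
                              (cell(seq_len(n_pos)) - 1L) * pool, `+`))
  structure(list(
    extractor_id = sprintf("randconv-v1-s%d-f%d", as.integer(seed),
                           pool^2 * n_filters),
    seed = as.integer(seed), input_size = as.integer(input_size),
    grid_size = as.integer(grid_size), patch = as.integer(patch),
    stride = as.integer(stride), n_filters = as.integer(n_filters),
    pool = as.integer(pool), n_features = as.integer(pool^2 * n_filters),
    weights = W, im2col_idx = idx, pos_cell = pos_cell,
    down = bilinear_matrix(grid_size, input_size)),
    class = "conv_backbone")
}

#' Extract a fixed-length feature vector from an auditory image
#'
#' @param image An `auditory_image` (from [render_image()]).
#' @param backbone A `conv_backbone` (see [random_backbone()]).
#' @return Numeric feature vector of length `backbone$n_features` with
#'   attribute `extractor_id`.
#' @export
extract_features <- function(image, backbone) {
  if (!inherits(backbone, "conv_backbone"))
    ss_abort("unknown backbone", "surgsound_unknown_backbone")
  stopifnot(inherits(image, "auditory_image"))
  d <- dim(image$pixels)
  if (d[1] != backbone$input_size || d[2] != backbone$input_size)
    ss_abort(sprintf("image is %dx%d but backbone expects %dx%d",
                     d[1], d[2], backbone$input_size, backbone$input_size),
             "surgsound_dim_mismatch")
  g <- backbone$down %*% image$pixels[, , 1L] %*% t(backbone$down)
  patches <- matrix(g[backbone$im2col_idx], nrow = backbone$patch^2)
  act <- pmax(crossprod(patches, backbone$weights), 0)  # positions x filters
  pooled <- rowsum(act, backbone$pos_cell) /
    as.vector(table(backbone$pos_cell))
  structure(as.numeric(pooled), extractor_id = backbone$extractor_id)
}

#' Softmax cross-entropy loss
#'
#' `H(y, p) = -sum_c y_c log(p_c)` per observation, natural log, with the
#' predicted probability clamped below at 1e-12.
#'
#' @param y One-hot truth: vector for one observation or `n x M` matrix.
#' @param p Predicted probabilities on the simplex, same shape as `y`.
#' @return Loss per observation (scalar or length-n vector).
#' @export
cross_entropy <- function(y, p) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  if (!all(dim(y) == dim(p)))
    ss_abort("y and p shapes differ", "surgsound_dim_mismatch")
  as.numeric(-rowSums(y * log(pmax(p, 1e-12))))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Training hyper-parameters for the softmax head
#'
#' @param batch_size Mini-batch size (the canonical 32).
#' @param learning_rate Fixed RMSprop learning rate.
#' @param max_epochs Epoch budget.
#' @param patience Early-stopping patience: epochs without validation-loss
#'   improvement before training stops. Must be below `max_epochs`.
#' @param seed Seed for batch shuffling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, learning_rate = 1e-3,
                         max_epochs = 100L, patience = 10L, seed = 1L) {
  if (batch_size < 1L) ss_abort("batch_size must be >= 1",
                                "surgsound_bad_config")
  if (learning_rate <= 0) ss_abort("learning_rate must be positive",
                                   "surgsound_bad_config")
  if (patience >= max_epochs) ss_abort("patience must be < max_epochs",
                                       "surgsound_bad_config")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = as.numeric(learning_rate),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

#' Assign clips to train/validation/test splits
#'
#' Splitting happens at CLIP level — all analysis windows of a clip share
#' one split — so that overlapping windows of the same recording can never
#' straddle the train/test boundary. Assignment is stratified by class and
#' deterministic given the seed.
#'
#' @param manifest Data frame with a `clip_id` column and either a `class`
#'   column or `tissue`/`mode` columns (then `scheme` is used).
#' @param fractions Numeric `(train, val, test)` fractions summing to 1.
#' @param seed Integer seed.
#' @param scheme Optional [label_scheme()] used to derive `class`.
#' @return The manifest with a `split` column
#'   (`"train"`/`"val"`/`"test"`).
#' @export
split_dataset <- function(manifest, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                          scheme = NULL) {
  if (abs(sum(fractions) - 1) > 1e-9)
    ss_abort("split fractions must sum to 1", "surgsound_bad_config")
  cls <- if (!is.null(scheme)) scheme_labels(manifest, scheme)
         else manifest$class
  if (is.null(cls)) ss_abort("manifest lacks class information",
                             "surgsound_bad_manifest")
  split <- character(nrow(manifest))
  with_local_seed(derive_seed(seed, "split"), {
    for (cl in unique(cls)) {
      rows <- which(cls == cl)
      ids <- unique(manifest$clip_id[rows])
      n <- length(ids)
      if (n < 3L)
        ss_abort(sprintf(
          "class '%s' has %d clip(s); need >= 3 to populate all splits",
          cl, n), "surgsound_sparse_class")
      ids <- sample(ids)
      n_test <- max(1L, round(fractions[3] * n))
      n_val <- max(1L, round(fractions[2] * n))
      assign_of <- c(rep("test", n_test), rep("val", n_val),
                     rep("train", n - n_test - n_val))
      names(assign_of) <- ids
      split[rows] <- assign_of[manifest$clip_id[rows]]
    }
  })
  manifest$split <- split
  manifest
}

#' Train the softmax classification head
#'
#' Multinomial logistic regression on frozen backbone features, optimized
#' by mini-batch RMSprop on the softmax cross-entropy loss with early
#' stopping on validation loss. Features are standardized per dimension
#' using training-set statistics stored inside the model. The weights of
#' the best validation epoch are returned.
#'
#' @param features `n x d` numeric feature matrix.
#' @param labels Character/factor labels, one per row of `features`.
#' @param split Character vector (`"train"`/`"val"`) aligned with rows;
#'   rows with other values are ignored.
#' @param scheme A [label_scheme()]; its class order fixes the output
#'   order.
#' @param config A [train_config()].
#' @return Object of class `head_model`: weights `W` (`d x M`), bias `b`,
#'   `label_scheme`, standardization stats, `training_log` (data frame of
#'   per-epoch train/val loss), `best_epoch`.
#' @export
train_head <- function(features, labels, split, scheme,
                       config = train_config()) {
  stopifnot(inherits(scheme, "label_scheme"),
            inherits(config, "train_config"))
  labels <- as.character(labels)
  classes <- scheme$classes
  if (!all(labels %in% classes))
    ss_abort("labels outside the scheme", "surgsound_unknown_label")
  tr <- which(split == "train"); va <- which(split == "val")
  if (!all(classes %in% labels[tr]))
    ss_abort("every class needs at least one training sample",
             "surgsound_empty_class")
  M <- length(classes); d <- ncol(features)

  mu <- colMeans(features[tr, , drop = FALSE])
  sd_ <- pmax(apply(features[tr, , drop = FALSE], 2L, stats::sd), 1e-8)
  Xtr <- sweep(sweep(features[tr, , drop = FALSE], 2L, mu), 2L, sd_, "/")
  Xva <- if (length(va))
    sweep(sweep(features[va, , drop = FALSE], 2L, mu), 2L, sd_, "/")
  Ytr <- outer(labels[tr], classes, `==`) * 1
  Yva <- if (length(va)) outer(labels[va], classes, `==`) * 1

  W <- matrix(0, d, M); b <- numeric(M)
  cW <- matrix(0, d, M); cb <- numeric(M)        # RMSprop caches
  rho <- 0.9; eps <- 1e-8; lr <- config$learning_rate
  n_tr <- length(tr)
  best <- list(loss = Inf, W = W, b = b, epoch = 0L)
  log_tr <- log_va <- numeric(0)
  stall <- 0L

  with_local_seed(derive_seed(config$seed, "train"), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0
      for (i0 in seq(1L, n_tr, by = config$batch_size)) {
        bi <- ord[i0:min(i0 + config$batch_size - 1L, n_tr)]
        Xb <- Xtr[bi, , drop = FALSE]; Yb <- Ytr[bi, , drop = FALSE]
        P <- softmax_rows(sweep(Xb %*% W, 2L, b, `+`))
        ep_loss <- ep_loss + sum(cross_entropy(Yb, P))
        G <- (P - Yb) / nrow(Xb)
        gW <- crossprod(Xb, G); gb <- colSums(G)
        cW <- rho * cW + (1 - rho) * gW^2
        cb <- rho * cb + (1 - rho) * gb^2
        W <- W - lr * gW / (sqrt(cW) + eps)
        b <- b - lr * gb / (sqrt(cb) + eps)
      }
      tr_loss <- ep_loss / n_tr
      if (!is.finite(tr_loss))
        ss_abort(sprintf("training diverged (non-finite loss at epoch %d)",
                         epoch), "surgsound_divergence")
      va_loss <- if (length(va)) {
        Pv <- softmax_rows(sweep(Xva %*% W, 2L, b, `+`))
        mean(cross_entropy(Yva, Pv))
      } else tr_loss
      log_tr[epoch] <- tr_loss; log_va[epoch] <- va_loss
      if (va_loss < best$loss - 1e-12) {
        best <- list(loss = va_loss, W = W, b = b, epoch = epoch)
        stall <- 0L
      } else stall <- stall + 1L
      if (stall >= config$patience) break
    }
  })

  structure(list(W = best$W, b = best$b, label_scheme = scheme,
                 feature_mean = mu, feature_sd = sd_,
                 training_log = data.frame(epoch = seq_along(log_tr),
                                           train_loss = log_tr,
                                           val_loss = log_va),
                 best_epoch = best$epoch, train_config = config),
            class = "head_model")
}

#' Predict class probabilities from features
#'
#' Softmax over the head's logits; ties in the argmax resolve to the
#' lowest class index.
#'
#' @param object A `head_model`.
#' @param features Numeric vector (one sample) or `n x d` matrix.
#' @param ... Unused.
#' @return List with `probabilities` (`n x M` matrix, rows sum to 1) and
#'   `labels` (argmax class names).
#' @export
predict.head_model <- function(object, features, ...) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (ncol(features) != nrow(object$W))
    ss_abort(sprintf("feature length %d does not match model (%d)",
                     ncol(features), nrow(object$W)),
             "surgsound_dim_mismatch")
  X <- sweep(sweep(features, 2L, object$feature_mean), 2L,
             object$feature_sd, "/")
  P <- softmax_rows(sweep(X %*% object$W, 2L, object$b, `+`))
  colnames(P) <- object$label_scheme$classes
  list(probabilities = P,
       labels = object$label_scheme$classes[apply(P, 1L, which.max)])
}

#' Save / load a self-describing model checkpoint
#'
#' The checkpoint carries everything needed to classify raw audio: head
#' weights, label scheme, the spectrogram configuration, normalization
#' statistics and the backbone description. Round-trips are exact.
#'
#' @param model A `head_model` (typically decorated by the pipeline with
#'   `spectrogram_config`, `norm_stats` and `backbone`).
#' @param path Destination file.
#' @return `save_model()`: `path` invisibly; `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "head_model"))
  obj <- list(format = "surgsound-checkpoint", version = 1L, model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    ss_abort(sprintf("no such checkpoint: %s", path),
             "surgsound_missing_file")
  obj <- readRDS(path)
  if (!identical(obj$format, "surgsound-checkpoint"))
    ss_abort("not a surgsound checkpoint", "surgsound_bad_checkpoint")
  obj$model
}
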