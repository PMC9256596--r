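#' Training configuration
#'
#' The optimizer schedule of the classifier: SGD with momentum 0.9 and
#' initial learning rate 1e-4, learning rate reduced by factor 0.2 on each
#' validation-loss plateau, early stopping when the validation loss has not
#' improved for `early_stop_patience` epochs, binary cross-entropy loss
#' plus the L2 kernel penalty, and padded batches of 32. Augmentation
#' draws a contrast factor, brightness offset and rotation angle per sample
#' per epoch.
#'
#' @param initial_lr Initial SGD learning rate.
#' @param momentum SGD momentum.
#' @param plateau_factor Learning-rate multiplier applied on a plateau.
#' @param plateau_patience Epochs without validation-loss improvement
#'   (by more than `min_delta`) that define a plateau.
#' @param early_stop_patience Epochs without improvement before stopping.
#' @param min_delta Minimum validation-loss improvement that resets the
#'   plateau and early-stopping counters.
#' @param batch_size Images per padded batch.
#' @param max_epochs Epoch cap (early stopping normally fires first).
#' @param contrast_range Uniform range of the contrast factor (about
#'   mid-gray).
#' @param brightness_range Uniform range of the additive brightness offset.
#' @param rotation_range Uniform range of the rotation angle in degrees.
#' @param seed Seed for split-independent training randomness.
#' @return An object of class `train_config`.
#' @export
train_config <- function(initial_lr = 1e-4, momentum = 0.9,
                         plateau_factor = 0.2, plateau_patience = 5L,
                         early_stop_patience = 10L, min_delta = 1e-4,
                         batch_size = 32L, max_epochs = 200L,
                         contrast_range = c(0.8, 1.2),
                         brightness_range = c(-0.1, 0.1),
                         rotation_range = c(0, 360),
                         seed = 1L) {
  stopifnot(initial_lr > 0, momentum >= 0, momentum < 1,
            plateau_factor > 0, plateau_factor < 1,
            plateau_patience >= 1, early_stop_patience >= 1,
            min_delta >= 0, batch_size >= 1, max_epochs >= 1,
            length(contrast_range) == 2, length(brightness_range) == 2,
            length(rotation_range) == 2)
  structure(as.list(environment()), class = "train_config")
}

#' Monte-Carlo case-level training/validation splits
#'
#' Draws `n_splits` independent random splits of the training cases.
#' Splitting is by case, never by image, so no case contributes images to
#' both folds of a split. Each validation fold is exactly 1 negative-class
#' (epilepsy/normal) case plus 4 positive-class (glioma/tumor) cases;
#' remaining cases train. Splits are drawn independently, so cases may
#' recur in different splits' validation folds.
#'
#' @param manifest A `case_manifest` (only `split_role == "train"` rows are
#'   used).
#' @param n_splits Number of Monte-Carlo splits.
#' @param seed RNG seed.
#' @param val_negative,val_positive Validation-fold case counts per class.
#' @return List of `split_spec` objects with `split_id`,
#'   `train_case_ids`, `val_case_ids`, `seed`.
#' @export
make_mc_splits <- function(manifest, n_splits = 10L, seed = 1L,
                           val_negative = 1L, val_positive = 4L) {
  stopifnot(inherits(manifest, "data.frame"), n_splits >= 1)
  tr <- manifest[manifest$split_role == "train", ]
  cases <- unique(tr[, c("case_id", "diagnosis")])
  neg <- cases$case_id[cases$diagnosis == "epilepsy"]
  pos <- cases$case_id[cases$diagnosis == "glioma"]
  if (length(neg) < val_negative + 1L || length(pos) < val_positive + 1L) {
    stop_thgqc("need at least ", val_negative + 1L, " negative and ",
               val_positive + 1L, " positive cases (got ", length(neg),
               " and ", length(pos), ")", class = "thgqc_value_error")
  }
  with_seed(seed, function() {
    lapply(seq_len(n_splits), function(i) {
      val <- c(sample(neg, val_negative), sample(pos, val_positive))
      structure(list(split_id = i,
                     train_case_ids = sort(setdiff(cases$case_id, val)),
                     val_case_ids = sort(val),
                     seed = derive_seed(seed, "split", i)),
                class = "split_spec")
    })
  })
}

#' Augment one image
#'
#' Draws a contrast factor (scaling about mid-gray 0.5), a brightness
#' offset and a rotation angle from the configured uniform ranges, applies
#' them and clips the result to \[0, 1\]. Rotation is about the image
#' center with bilinear interpolation and reflected boundary padding;
#' multiples of 90 degrees use the exact array permutation.
#'
#' @param image Numeric matrix scaled to \[0, 1\].
#' @param config A [train_config()] supplying the ranges.
#' @return Augmented matrix of the same shape, in \[0, 1\].
#' @export
augment_image <- function(image, config = train_config()) {
  stopifnot(is.matrix(image))
  cr <- config$contrast_range
  br <- config$brightness_range
  rr <- config$rotation_range
  if (cr[2] + max(abs(br)) < 0.05) {
    warning("augmentation ranges can only produce near-black output")
  }
  contrast <- runif(1, cr[1], cr[2])
  brightness <- runif(1, br[1], br[2])
  angle <- runif(1, rr[1], rr[2])
  out <- rotate_reflect(image, angle)
  out <- 0.5 + contrast * (out - 0.5) + brightness
  pmin(pmax(out, 0), 1)
}

#' Rotate a matrix about its center with reflect padding
#'
#' @param m Numeric matrix.
#' @param angle Rotation angle in degrees (counter-clockwise in standard
#'   plot orientation).
#' @return Rotated matrix of the same shape.
#' @export
rotate_reflect <- function(m, angle) {
  angle <- angle %% 360
  if (isTRUE(all.equal(angle, 0))) return(m)
  if (isTRUE(all.equal(angle %% 90, 0))) {
    k <- round(angle / 90) %% 4
    rot90 <- function(x) t(x)[ncol(x):1, , drop = FALSE]
    for (i in seq_len(k)) m <- rot90(m)
    return(m)
  }
  H <- nrow(m); W <- ncol(m)
  th <- angle * pi / 180
  ci <- (H + 1) / 2; cj <- (W + 1) / 2
  gi <- rep(seq_len(H), times = W) - ci
  gj <- rep(seq_len(W), each = H) - cj
  # inverse mapping: source coordinates for each destination pixel
  si <- cos(th) * gi + sin(th) * gj + ci
  sj <- -sin(th) * gi + cos(th) * gj + cj
  reflect <- function(x, n) {
    # reflect about the [1, n] interval (cell-edge symmetric)
    x <- (x - 1) %% (2 * (n - 1))
    ifelse(x > (n - 1), 2 * (n - 1) - x, x) + 1
  }
  si <- reflect(si, H); sj <- reflect(sj, W)
  i0 <- pmin(pmax(floor(si), 1), H - 1); j0 <- pmin(pmax(floor(sj), 1), W - 1)
  fi <- si - i0; fj <- sj - j0
  idx <- function(i, j) (j - 1L) * H + i
  v <- (1 - fi) * (1 - fj) * m[idx(i0, j0)] +
    fi * (1 - fj) * m[idx(i0 + 1L, j0)] +
    (1 - fi) * fj * m[idx(i0, j0 + 1L)] +
    fi * fj * m[idx(i0 + 1L, j0 + 1L)]
  matrix(v, H, W)
}

#' Build one balanced, augmented, padded epoch stream
#'
#' Oversamples the minority class with replacement until both classes have
#' equal counts, shuffles, augments every drawn sample independently, and
#' packs the result into batches zero-padded per batch to the batch's
#' maximum height and width. Each call draws fresh oversampling and
#' augmentations, so successive epochs differ.
#'
#' @param images List of numeric matrices scaled to \[0, 1\].
#' @param labels Numeric 0/1 vector (1 = tumor).
#' @param config A [train_config()].
#' @param augment Apply photometric/rotation augmentation.
#' @return List of batches, each `list(x = list of padded matrices, y =
#'   labels)`; attribute `epoch_size` gives the balanced sample count.
#' @export
make_epoch_stream <- function(images, labels, config = train_config(),
                              augment = TRUE) {
  stopifnot(length(images) == length(labels))
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2) {
    stop_thgqc("epoch stream needs both classes present",
               class = "thgqc_value_error")
  }
  pos <- which(labels == 1); neg <- which(labels == 0)
  n_per_class <- max(length(pos), length(neg))
  draw <- function(idx) {
    if (length(idx) == n_per_class) idx
    else c(idx, sample(idx, n_per_class - length(idx), replace = TRUE))
  }
  order_idx <- sample(c(draw(pos), draw(neg)))
  batches <- split(order_idx,
                   ceiling(seq_along(order_idx) / config$batch_size))
  out <- lapply(batches, function(b) {
    xs <- lapply(images[b], function(m) {
      if (augment) augment_image(m, config) else m
    })
    hh <- max(vapply(xs, nrow, integer(1)))
    ww <- max(vapply(xs, ncol, integer(1)))
    xs <- lapply(xs, function(m) {
      if (nrow(m) == hh && ncol(m) == ww) return(m)
      p <- matrix(0, hh, ww)
      p[seq_len(nrow(m)), seq_len(ncol(m))] <- m
      p
    })
    list(x = xs, y = labels[b])
  })
  attr(out, "epoch_size") <- length(order_idx)
  out
}

#' Train the classifier on one Monte-Carlo split
#'
#' Runs the full optimization loop: per-epoch balanced and uniquely
#' augmented streams for both the training and validation fold, SGD with
#' momentum, learning-rate reduction by `plateau_factor` on each
#' validation-loss plateau, early stopping, and checkpointing of the
#' weights at the lowest validation loss. The recorded validation accuracy
#' (threshold 0.5) and AUC are those of the checkpoint epoch. Validation
#' scores are computed in inference mode.
#'
#' @param model A [build_fcn()] model (initial weights).
#' @param train_images,train_labels Training-fold matrices in \[0, 1\] and
#'   0/1 labels (after any quality exclusion).
#' @param val_images,val_labels Validation fold (never quality-filtered).
#' @param config A [train_config()].
#' @param seed Seed controlling epoch streams.
#' @param verbose Print per-epoch progress.
#' @return An object of class `thg_fcn_fit`: `model` (checkpoint),
#'   `history` (per-epoch data frame), `best_epoch`, `val_loss`,
#'   `val_accuracy`, `val_auc`, `val_accuracy_raw`, `val_auc_raw`.
#' @export
train_fcn <- function(model, train_images, train_labels,
                      val_images, val_labels,
                      config = train_config(), seed = config$seed,
                      verbose = FALSE) {
  stopifnot(inherits(model, "thg_fcn"))
  if (length(train_images) == 0) {
    stop_thgqc("no training data (all images excluded by the quality ",
               "condition?)", class = "thgqc_value_error")
  }
  lr <- config$initial_lr
  state <- new.env(parent = emptyenv())
  best <- list(loss = Inf, epoch = 0L, model = model,
               accuracy = NA_real_, auc = NA_real_)
  since_improve <- 0L
  hist <- list()
  for (epoch in seq_len(config$max_epochs)) {
    epoch_seed <- derive_seed(seed, "epoch", epoch)
    stream <- with_seed(epoch_seed, function()
      make_epoch_stream(train_images, train_labels, config))
    train_loss <- 0; n_batches <- 0L
    for (batch in stream) {
      fwd <- fcn_forward_train(model, batch$x)
      model <- fwd$model
      loss <- fcn_loss(model, fwd$scores, batch$y)
      dlogits <- (fwd$scores - batch$y) / length(batch$y)
      grads <- fcn_backward(model, fwd, dlogits)
      stepped <- fcn_sgd_step(model, grads, state, lr, config$momentum)
      model <- stepped$model
      train_loss <- train_loss + loss
      n_batches <- n_batches + 1L
    }
    train_loss <- train_loss / n_batches
    # balanced, augmented validation stream; scores in inference mode
    val_stream <- with_seed(derive_seed(seed, "val", epoch), function()
      make_epoch_stream(val_images, val_labels, config))
    vs <- unlist(lapply(val_stream, function(b)
      vapply(b$x, function(m) fcn_forward_infer(model, m)$score, numeric(1))))
    vy <- unlist(lapply(val_stream, `[[`, "y"))
    val_loss <- fcn_loss(model, vs, vy)
    val_acc <- mean((vs >= 0.5) == (vy == 1))
    val_auc <- roc_auc(scored_set(vs, vy))$auc
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                train_loss = train_loss,
                                val_loss = val_loss,
                                val_accuracy = val_acc, val_auc = val_auc)
    if (verbose) {
      message(sprintf(
        "epoch %3d lr %.2g train %.4f val %.4f acc %.3f auc %.3f",
        epoch, lr, train_loss, val_loss, val_acc, val_auc))
    }
    if (val_loss < best$loss - config$min_delta) {
      best <- list(loss = val_loss, epoch = epoch, model = model,
                   accuracy = val_acc, auc = val_auc)
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve %% config$plateau_patience == 0L) {
        lr <- lr * config$plateau_factor
      }
      if (since_improve >= config$early_stop_patience) break
    }
  }
  history <- do.call(rbind, hist)
  # raw (unbalanced, unaugmented) validation metrics of the checkpoint
  raw_scores <- vapply(val_images, function(m)
    fcn_forward_infer(best$model, m)$score, numeric(1))
  raw_acc <- mean((raw_scores >= 0.5) == (val_labels == 1))
  raw_auc <- if (length(unique(val_labels)) == 2)
    roc_auc(scored_set(raw_scores, val_labels))$auc else NA_real_
  structure(list(model = best$model, history = history,
                 best_epoch = best$epoch, val_loss = best$loss,
                 val_accuracy = best$accuracy, val_auc = best$auc,
                 val_accuracy_raw = raw_acc, val_auc_raw = raw_auc,
                 val_scores_raw = raw_scores, val_labels = val_labels,
                 config = config, seed = seed),
            class = "thg_fcn_fit")
}

#' @export
print.thg_fcn_fit <- function(x, ...) {
  cat(sprintf(paste0("THG FCN fit: %d epochs, checkpoint at epoch %d\n",
                     "  val loss %.4f, val accuracy %.3f, val AUC %.3f\n"),
              nrow(x$history), x$best_epoch, x$val_loss,
              x$val_accuracy, x$val_auc))
  invisible(x)
}

#' @export
plot.thg_fcn_fit <- function(x, ...) {
  matplot(x$history$epoch,
          cbind(x$history$train_loss, x$history$val_loss),
          type = "l", lty = 1, col = c("steelblue", "firebrick"),
          xlab = "epoch", ylab = "loss (BCE + L2)", ...)
  abline(v = x$best_epoch, lty = 3)
  legend("topright", c("train", "validation"), lty = 1,
         col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
predict.thg_fcn_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' Run the condition-sweep training experiment
#'
#' For every quality condition and every Monte-Carlo split, applies the
#' condition to the split's training fold (validation folds are never
#' filtered), trains a model, and tabulates the per-condition mean and
#' standard deviation of the checkpoint validation accuracy (threshold
#' 0.5) and AUC. The best condition is flagged by mean AUC.
#'
#' @param images Named list of preprocessed image matrices in \[0, 1\],
#'   keyed by image id (see [manifest_image_ids()]).
#' @param manifest A `case_manifest` covering those images.
#' @param conditions List of [quality_condition()]s.
#' @param n_splits Monte-Carlo splits per condition.
#' @param model_config An [fcn_config()].
#' @param config A [train_config()].
#' @param seed Master seed.
#' @param splits Optional list of pre-drawn [make_mc_splits()] splits;
#'   drawn from `seed` when omitted.
#' @param verbose Print progress.
#' @return A `condition_experiment` data frame with one row per condition
#'   (`condition`, `n_excluded`, mean/sd accuracy and AUC, `best` flag);
#'   per-fit results are attached as attribute `fits`.
#' @export
run_condition_experiment <- function(images, manifest,
                                     conditions = default_conditions(),
                                     n_splits = 10L,
                                     model_config = fcn_config(),
                                     config = train_config(),
                                     seed = 1L, splits = NULL,
                                     verbose = FALSE) {
  tr <- manifest[manifest$split_role == "train", ]
  ids <- manifest_image_ids(tr)
  stopifnot(all(ids %in% names(images)))
  splits <- splits %||%
    make_mc_splits(manifest, n_splits, seed = derive_seed(seed, "splits"))
  n_splits <- length(splits)
  rows <- list()
  all_fits <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    qc <- apply_quality_condition(images[ids], cond, ids = ids)
    keep_ids <- qc$id[!qc$excluded]
    accs <- numeric(n_splits); aucs <- numeric(n_splits)
    accs_raw <- numeric(n_splits); aucs_raw <- numeric(n_splits)
    fits <- vector("list", n_splits)
    for (si in seq_len(n_splits)) {
      sp <- splits[[si]]
      tr_rows <- tr[tr$case_id %in% sp$train_case_ids, ]
      va_rows <- tr[tr$case_id %in% sp$val_case_ids, ]
      tr_ids <- intersect(manifest_image_ids(tr_rows), keep_ids)
      va_ids <- manifest_image_ids(va_rows)
      if (length(tr_ids) == 0) {
        stop_thgqc("condition ", format(cond), " excludes the entire ",
                   "training fold of split ", si,
                   class = "thgqc_value_error")
      }
      tr_lab <- as.numeric(tr$label[match(tr_ids, ids)] == "tumor")
      va_lab <- as.numeric(tr$label[match(va_ids, ids)] == "tumor")
      model <- build_fcn(model_config, seed = derive_seed(seed, "init", ci, si))
      fit <- train_fcn(model, images[tr_ids], tr_lab,
                       images[va_ids], va_lab, config,
                       seed = derive_seed(seed, "train", ci, si),
                       verbose = verbose)
      accs[si] <- fit$val_accuracy
      aucs[si] <- fit$val_auc
      accs_raw[si] <- fit$val_accuracy_raw
      aucs_raw[si] <- fit$val_auc_raw
      fits[[si]] <- fit
      if (verbose) {
        message(sprintf("condition %s split %d: acc %.3f auc %.3f (epoch %d)",
                        format(cond), si, fit$val_accuracy, fit$val_auc,
                        fit$best_epoch))
      }
    }
    rows[[ci]] <- data.frame(
      condition = format(cond),
      n_excluded = attr(qc, "n_excluded"),
      fraction_excluded = attr(qc, "fraction_excluded"),
      accuracy_mean = mean(accs), accuracy_sd = sd(accs),
      auc_mean = mean(aucs), auc_sd = sd(aucs),
      accuracy_raw_mean = mean(accs_raw),
      auc_raw_mean = mean(aucs_raw),
      auc_raw_sd = sd(aucs_raw))
    all_fits[[format(cond)]] <- fits
  }
  out <- do.call(rbind, rows)
  out$best <- seq_len(nrow(out)) == which.max(out$auc_mean)
  attr(out, "fits") <- all_fits
  class(out) <- c("condition_experiment", "data.frame")
  out
}

#' Stable per-row image identifiers of a manifest
#'
#' `image_path` for single images, `image_path#depth_index` for stack
#' slices; used to key image lists in experiments.
#'
#' @param manifest A `case_manifest` (or subset of rows).
#' @return Character vector of ids.
#' @export
manifest_image_ids <- function(manifest) {
  di <- if ("depth_index" %in% names(manifest)) manifest$depth_index
        else rep(NA_integer_, nrow(manifest))
  paste0(manifest$image_path, ifelse(is.na(di), "", paste0("#", di)))
}

#' Load and preprocess every training image of a manifest
#'
#' Reads each manifest row's image (resolving stack slices by depth
#' index), preprocesses it, and returns matrices scaled to \[0, 1\] keyed
#' by [manifest_image_ids()].
#'
#' @param manifest A `case_manifest`.
#' @param root Directory that `image_path` entries are relative to.
#' @param config A [preprocess_config()].
#' @return Named list of numeric matrices in \[0, 1\].
#' @export
load_manifest_images <- function(manifest, root = ".",
                                 config = preprocess_config()) {
  ids <- manifest_image_ids(manifest)
  out <- vector("list", nrow(manifest))
  names(out) <- ids
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(manifest))) {
    path <- manifest$image_path[i]
    px <- if ("pixel_size_um" %in% names(manifest))
      manifest$pixel_size_um[i] else NULL
    key <- path
    if (!exists(key, cache)) {
      assign(key, read_thg_image(file.path(root, path), pixel_size_um = px,
                                 case_id = manifest$case_id[i]),
             cache)
    }
    obj <- get(key, cache)
    rec <- if (inherits(obj, "zstack")) {
      di <- manifest$depth_index[i]
      obj$slices[[which(vapply(obj$slices, function(s) s$depth_index,
                               numeric(1)) == di)]]
    } else obj
    pp <- preprocess_image(rec, config)
    out[[i]] <- pp$pixels / 255
  }
  out
}
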