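#' Sliding-window score map of a mosaic
#'
#' Slides a square window over the mosaic on a stride grid, scores every
#' (fully contained) window with the classifier, and accumulates per-pixel
#' score sums and coverage counts; the mean score map is the accumulated
#' sum divided by the coverage. Stride 1 yields the smooth per-pixel
#' overlay; larger strides trade smoothness for speed. Partial windows at
#' the right/bottom edges are skipped, so with a stride larger than the
#' window some pixels may be uncovered (flagged by a warning) and carry
#' `NA` mean scores.
#'
#' Windows are scaled to \[0, 1\] by the mosaic bit depth before scoring,
#' identically to training inputs.
#'
#' @param mosaic A [thg_mosaic()] / [image_record()], or a numeric matrix
#'   already in \[0, 1\].
#' @param model A `thg_fcn`, `thg_fcn_fit`, or a function taking a window
#'   matrix and returning a score in \[0, 1\] (useful for testing).
#' @param window_size Window side length in pixels (>= the model minimum).
#' @param stride Grid stride in pixels (>= 1).
#' @return An object of class `score_map`: `mean_score` (matrix, `NA`
#'   where uncovered), `coverage_count` (integer matrix), `score_sum`,
#'   `window_size`, `stride`, and `window_scores` (per-position data
#'   frame).
#' @export
sliding_window_scores <- function(mosaic, model, window_size = 256L,
                                  stride = 8L) {
  if (inherits(mosaic, "image_record")) {
    m <- mosaic$pixels / (2^mosaic$bit_depth - 1)
  } else {
    m <- mosaic
  }
  stopifnot(is.matrix(m), stride >= 1)
  H <- nrow(m); W <- ncol(m)
  if (H < window_size || W < window_size) {
    stop_thgqc("mosaic ", H, "x", W, " smaller than the ", window_size,
               " px window", class = "thgqc_size_error")
  }
  score_fun <- if (is.function(model)) {
    model
  } else {
    mdl <- if (inherits(model, "thg_fcn_fit")) model$model else model
    stopifnot(inherits(mdl, "thg_fcn"))
    if (window_size < fcn_min_input(mdl)) {
      stop_thgqc("window_size below the model minimum of ",
                 fcn_min_input(mdl), " px", class = "thgqc_size_error")
    }
    function(w) fcn_forward_infer(mdl, w)$score
  }
  if (stride > window_size) {
    warning("stride exceeds the window size; some pixels will be uncovered")
  }
  rows <- seq(1L, H - window_size + 1L, by = stride)
  cols <- seq(1L, W - window_size + 1L, by = stride)
  score_sum <- matrix(0, H, W)
  coverage <- matrix(0L, H, W)
  pos <- expand.grid(row = rows, col = cols)
  scores <- numeric(nrow(pos))
  for (k in seq_len(nrow(pos))) {
    i <- pos$row[k]; j <- pos$col[k]
    ri <- i:(i + window_size - 1L)
    rj <- j:(j + window_size - 1L)
    s <- score_fun(m[ri, rj])
    scores[k] <- s
    score_sum[ri, rj] <- score_sum[ri, rj] + s
    coverage[ri, rj] <- coverage[ri, rj] + 1L
  }
  mean_score <- score_sum / coverage
  mean_score[coverage == 0L] <- NA_real_
  structure(list(mean_score = mean_score, coverage_count = coverage,
                 score_sum = score_sum, window_size = window_size,
                 stride = stride,
                 window_scores = cbind(pos, score = scores)),
            class = "score_map")
}

#' @export
print.score_map <- function(x, ...) {
  cat(sprintf(paste0("<score_map %dx%d px, window %d, stride %d, ",
                     "%d windows, mean score %.3f>\n"),
              nrow(x$mean_score), ncol(x$mean_score), x$window_size,
              x$stride, nrow(x$window_scores),
              mean(x$mean_score, na.rm = TRUE)))
  invisible(x)
}

#' Binarize a score map into a class mask
#'
#' Covered pixels with mean score at or above the threshold become tumor
#' (2), below become normal (1); uncovered pixels are background (0). The
#' threshold normally comes from the model's Youden calibration.
#'
#' @param score_map A `score_map`.
#' @param threshold Decision threshold in \[0, 1\].
#' @return Integer class-code matrix.
#' @export
binarize_overlay <- function(score_map, threshold = 0.5) {
  stopifnot(inherits(score_map, "score_map"),
            threshold >= 0, threshold <= 1)
  ms <- score_map$mean_score
  mask <- matrix(0L, nrow(ms), ncol(ms))
  covered <- score_map$coverage_count > 0L
  mask[covered] <- ifelse(ms[covered] >= threshold, 2L, 1L)
  mask
}

#' Per-class Jaccard index (intersection over union)
#'
#' Computes `|pred intersect ref| / |pred union ref|` over the pixel sets
#' of each tissue class. Background pixels (code 0) belong to neither
#' set. A class absent from both masks (empty union) yields an `NaN`
#' sentinel.
#'
#' @param pred_mask,ref_mask Integer class-code matrices of equal shape
#'   (0 background, 1 normal, 2 tumor).
#' @return An object of class `classwise_iou` with `iou_normal` and
#'   `iou_tumor`.
#' @export
jaccard_per_class <- function(pred_mask, ref_mask) {
  if (!identical(dim(pred_mask), dim(ref_mask))) {
    stop_thgqc("mask shapes differ", class = "thgqc_value_error")
  }
  iou <- function(code) {
    p <- pred_mask == code
    r <- ref_mask == code
    u <- sum(p | r)
    if (u == 0) NaN else sum(p & r) / u
  }
  structure(list(iou_normal = iou(1L), iou_tumor = iou(2L)),
            class = "classwise_iou")
}

#' @export
print.classwise_iou <- function(x, ...) {
  cat(sprintf("<IOU normal %.3f, tumor %.3f>\n", x$iou_normal, x$iou_tumor))
  invisible(x)
}
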