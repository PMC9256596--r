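#' A set of scored images with reference labels
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param labels 0/1 labels (1 = tumor/positive).
#' @param ids Optional image identifiers.
#' @return An object of class `scored_set`.
#' @export
scored_set <- function(scores, labels, ids = NULL) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0, 1)))
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    stop_thgqc("scores must be finite and in [0,1]",
               class = "thgqc_value_error")
  }
  structure(list(scores = as.numeric(scores), labels = labels,
                 ids = ids %||% as.character(seq_along(scores))),
            class = "scored_set")
}

as_scored <- function(x) {
  if (inherits(x, "scored_set")) x else scored_set(x$scores, x$labels, x$ids)
}

# Confusion counts under the fixed decision rule: score >= threshold
# predicts positive (closed on the positive side).
confusion_at <- function(scores, labels, threshold) {
  pred <- scores >= threshold
  c(tp = sum(pred & labels == 1), fp = sum(pred & labels == 0),
    fn = sum(!pred & labels == 1), tn = sum(!pred & labels == 0))
}

#' ROC curve and area under it
#'
#' Sweeps thresholds over the unique scores (plus an all-negative
#' sentinel), computing (FPR, TPR) points under the rule "score >=
#' threshold is positive"; tied scores enter together. The AUC is the
#' trapezoidal integral of the curve, which equals the normalized
#' Mann-Whitney concordance statistic (ties counted 1/2).
#'
#' @param scored A [scored_set()].
#' @return An object of class `roc_result`: data frame `points` with
#'   `threshold`, `fpr`, `tpr`, and scalar `auc`.
#' @export
roc_auc <- function(scored) {
  s <- as_scored(scored)
  n_pos <- sum(s$labels == 1); n_neg <- sum(s$labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop_thgqc("ROC undefined: both classes must be present",
               class = "thgqc_metric_error")
  }
  th <- c(Inf, sort(unique(s$scores), decreasing = TRUE))
  pts <- t(vapply(th, function(t) {
    cm <- confusion_at(s$scores, s$labels, t)
    c(fpr = cm[["fp"]] / n_neg, tpr = cm[["tp"]] / n_pos)
  }, numeric(2)))
  points <- data.frame(threshold = th, fpr = pts[, 1], tpr = pts[, 2])
  auc <- sum(diff(points$fpr) *
               (head(points$tpr, -1) + tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc), class = "roc_result")
}

#' Precision-recall curve and average precision
#'
#' Precision-recall points over the descending threshold sweep; average
#' precision is the step-interpolated sum `AP = sum((R_k - R_{k-1}) *
#' P_k)`, the conservative convention for PR curves.
#'
#' @param scored A [scored_set()].
#' @return An object of class `pr_result`: data frame `points` with
#'   `threshold`, `recall`, `precision`, and scalar `ap`.
#' @export
pr_ap <- function(scored) {
  s <- as_scored(scored)
  n_pos <- sum(s$labels == 1)
  if (n_pos == 0) {
    stop_thgqc("average precision undefined without positives",
               class = "thgqc_metric_error")
  }
  th <- sort(unique(s$scores), decreasing = TRUE)
  pts <- t(vapply(th, function(t) {
    cm <- confusion_at(s$scores, s$labels, t)
    prec <- if (cm[["tp"]] + cm[["fp"]] > 0)
      cm[["tp"]] / (cm[["tp"]] + cm[["fp"]]) else 1
    c(recall = cm[["tp"]] / n_pos, precision = prec)
  }, numeric(2)))
  points <- data.frame(threshold = th, recall = pts[, 1],
                       precision = pts[, 2])
  ap <- sum(diff(c(0, points$recall)) * points$precision)
  structure(list(points = points, ap = ap), class = "pr_result")
}

#' No-skill average-precision baseline
#'
#' The average precision of a no-skill classifier equals the class
#' prevalence: `n_positive / n_total`.
#'
#' @param n_positive,n_total Positive and total example counts.
#' @return Scalar prevalence.
#' @export
no_skill_ap <- function(n_positive, n_total) {
  stopifnot(n_total > 0, n_positive >= 0, n_positive <= n_total)
  n_positive / n_total
}

#' Youden-optimal classification threshold
#'
#' Returns the threshold maximizing Youden's J = TPR - FPR = sensitivity +
#' specificity - 1 over the ROC candidate thresholds, breaking ties by the
#' lowest qualifying threshold. If no threshold achieves J > 0 (an
#' uninformative or anti-correlated ranking) the lowest candidate is
#' returned with a warning.
#'
#' @param roc A `roc_result` from [roc_auc()].
#' @return Scalar threshold.
#' @export
youden_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  pts <- roc$points[is.finite(roc$points$threshold), ]
  j <- pts$tpr - pts$fpr
  best <- max(j)
  if (best <= 0) {
    warning("no informative threshold: maximum Youden J is ", signif(best, 3))
  }
  cand <- pts$threshold[j >= best - 1e-12]
  min(cand)
}

#' Threshold-calibrated binary metrics
#'
#' Accuracy, sensitivity (TPR) and specificity (1 - FPR) of the decision
#' rule "score >= threshold is positive".
#'
#' @param scored A [scored_set()].
#' @param threshold Decision threshold.
#' @return An object of class `metrics_summary`.
#' @export
metrics_at_threshold <- function(scored, threshold) {
  s <- as_scored(scored)
  cm <- confusion_at(s$scores, s$labels, threshold)
  sens <- if (cm[["tp"]] + cm[["fn"]] > 0)
    cm[["tp"]] / (cm[["tp"]] + cm[["fn"]]) else NaN
  spec <- if (cm[["tn"]] + cm[["fp"]] > 0)
    cm[["tn"]] / (cm[["tn"]] + cm[["fp"]]) else NaN
  structure(list(threshold = threshold,
                 accuracy = (cm[["tp"]] + cm[["tn"]]) / sum(cm),
                 sensitivity = sens, specificity = spec,
                 confusion = cm),
            class = "metrics_summary")
}

#' @export
print.metrics_summary <- function(x, ...) {
  cat(sprintf(paste0("<metrics at threshold %.4g: accuracy %.3f, ",
                     "sensitivity %.3f, specificity %.3f>\n"),
              x$threshold, x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' Vertically average an ensemble of curves
#'
#' Interpolates each member curve onto a common abscissa grid and returns
#' the pointwise mean and population variance (divisor n), the way
#' ensemble mean ROC/PR curves with variance bands are reported. The
#' bundle's scalar AUC/AP is the mean of the member scalars, not the
#' integral of the mean curve.
#'
#' @param curves List of `roc_result` or `pr_result` objects (>= 2).
#' @param grid_size Number of grid points.
#' @param variance_divisor `"n"` (population, default) or `"n-1"`.
#' @return An object of class `curve_bundle`: `grid`, `mean`, `variance`,
#'   `members` (interpolated member ordinates), and `mean_score` (mean
#'   member AUC/AP).
#' @export
aggregate_curves <- function(curves, grid_size = 101L,
                             variance_divisor = c("n", "n-1")) {
  variance_divisor <- match.arg(variance_divisor)
  if (length(curves) < 2) {
    stop_thgqc("need at least 2 curves to aggregate",
               class = "thgqc_value_error")
  }
  is_roc <- inherits(curves[[1]], "roc_result")
  grid <- seq(0, 1, length.out = grid_size)
  interp_one <- function(cv) {
    if (is_roc) {
      x <- cv$points$fpr; y <- cv$points$tpr
    } else {
      x <- cv$points$recall; y <- cv$points$precision
    }
    o <- order(x, y)
    x <- x[o]; y <- y[o]
    # ensure the curve spans [0,1] on the abscissa
    if (min(x) > 0) { x <- c(0, x); y <- c(y[1], y) }
    if (max(x) < 1) { x <- c(x, 1); y <- c(y, y[length(y)]) }
    approx(x, y, xout = grid, ties = if (is_roc) max else min)$y
  }
  members <- vapply(curves, interp_one, numeric(grid_size))
  mu <- rowMeans(members)
  va <- rowMeans((members - mu)^2)
  if (variance_divisor == "n-1") {
    va <- va * length(curves) / (length(curves) - 1)
  }
  scores <- vapply(curves, function(cv) cv$auc %||% cv$ap, numeric(1))
  structure(list(grid = grid, mean = mu, variance = va, members = members,
                 mean_score = mean(scores), kind = if (is_roc) "roc" else "pr"),
            class = "curve_bundle")
}

#' Evaluate an ensemble of models on a test set
#'
#' Scores every test image with every model, computes per-model ROC/AUC
#' and PR/AP, derives each model's own Youden threshold from its own
#' test-set ROC (mirroring per-model operating-point calibration;
#' alternatively a fixed threshold can be supplied, the deployment-honest
#' choice), and reports per-model and averaged accuracy, sensitivity and
#' specificity, plus mean ROC and PR curve bundles.
#'
#' @param models List of `thg_fcn` or `thg_fcn_fit` objects.
#' @param images List of test image matrices in \[0, 1\].
#' @param labels 0/1 test labels.
#' @param threshold `"youden"` (per-model, from its own test ROC) or a
#'   fixed numeric threshold.
#' @return An object of class `ensemble_evaluation` with `per_model` (data
#'   frame), `mean_roc`, `mean_pr` (curve bundles) and `summary` (named
#'   means and sds).
#' @export
evaluate_ensemble <- function(models, images, labels,
                              threshold = "youden") {
  score_one <- function(m) {
    mdl <- if (inherits(m, "thg_fcn_fit")) m$model else m
    predict(mdl, images)
  }
  rows <- list()
  rocs <- list(); prs <- list()
  for (i in seq_along(models)) {
    sc <- scored_set(score_one(models[[i]]), labels)
    roc <- roc_auc(sc)
    pr <- pr_ap(sc)
    th <- if (identical(threshold, "youden")) youden_threshold(roc)
          else threshold
    met <- metrics_at_threshold(sc, th)
    rows[[i]] <- data.frame(model = i, auc = roc$auc, ap = pr$ap,
                            threshold = th, accuracy = met$accuracy,
                            sensitivity = met$sensitivity,
                            specificity = met$specificity)
    rocs[[i]] <- roc; prs[[i]] <- pr
  }
  per_model <- do.call(rbind, rows)
  agg <- function(v) c(mean = mean(v), sd = sd(v))
  structure(list(
    per_model = per_model,
    mean_roc = if (length(models) >= 2) aggregate_curves(rocs) else NULL,
    mean_pr = if (length(models) >= 2) aggregate_curves(prs) else NULL,
    summary = list(auc = agg(per_model$auc), ap = agg(per_model$ap),
                   accuracy = agg(per_model$accuracy),
                   sensitivity = agg(per_model$sensitivity),
                   specificity = agg(per_model$specificity))),
    class = "ensemble_evaluation")
}

#' @export
print.ensemble_evaluation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("Ensemble of %d models:\n",
                     "  AUC %.3f +/- %.3f, AP %.3f +/- %.3f\n",
                     "  accuracy %.1f%% +/- %.1f%%, sensitivity %.1f%%, ",
                     "specificity %.1f%%\n"),
              nrow(x$per_model),
              s$auc[["mean"]], s$auc[["sd"]], s$ap[["mean"]], s$ap[["sd"]],
              100 * s$accuracy[["mean"]], 100 * s$accuracy[["sd"]],
              100 * s$sensitivity[["mean"]], 100 * s$specificity[["mean"]]))
  invisible(x)
}
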