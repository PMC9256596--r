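#' Experiment configuration for the full pipeline
#'
#' Collects every stage's settings plus a master seed. Each stage derives
#' its own RNG stream from the master seed and its stage name, so stages
#' are individually reproducible. The configuration round-trips through
#' YAML serialization unchanged.
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Master seed.
#' @param dataset A [dataset_spec()] (for the simulate stage).
#' @param phantom A [phantom_params()].
#' @param preprocess A [preprocess_config()].
#' @param conditions List of [quality_condition()]s for the sweep.
#' @param model An [fcn_config()].
#' @param train A [train_config()].
#' @param n_splits Monte-Carlo splits per condition.
#' @param overlay List with `window_size`, `stride` and `threshold`
#'   (`"youden"` or numeric) for the segment stage.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(out_dir, seed = 1L,
                              dataset = dataset_spec(seed = seed),
                              phantom = phantom_params(seed = seed),
                              preprocess = preprocess_config(),
                              conditions = default_conditions(),
                              model = fcn_config(),
                              train = train_config(),
                              n_splits = 10L,
                              overlay = list(window_size = 64L, stride = 16L,
                                             threshold = "youden")) {
  stopifnot(is.character(out_dir), length(out_dir) == 1)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 dataset = dataset, phantom = phantom,
                 preprocess = preprocess, conditions = conditions,
                 model = model, train = train,
                 n_splits = as.integer(n_splits), overlay = overlay),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Unspecified fields fall back to the package defaults. Constructor
#' validation runs on every field, so an invalid file fails before any
#' compute.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) {
    stop_thgqc("config not found: ", path, class = "thgqc_not_found_error")
  }
  y <- yaml::read_yaml(path)
  if (is.null(y$out_dir)) {
    stop_thgqc("config must set out_dir", class = "thgqc_validation_error")
  }
  seed <- as.integer(y$seed %||% 1L)
  build <- function(ctor, args) do.call(ctor, args %||% list())
  conds <- if (is.null(y$conditions)) default_conditions()
  else lapply(y$conditions, function(cc)
    quality_condition(cc$freq_frac %||% NA, cc$kurtosis_cutoff %||% NA))
  experiment_config(
    out_dir = y$out_dir, seed = seed,
    dataset = build(dataset_spec, c(y$dataset,
                                    if (is.null(y$dataset$seed)) list(seed = seed))),
    phantom = build(phantom_params, c(y$phantom,
                                      if (is.null(y$phantom$seed)) list(seed = seed))),
    preprocess = build(preprocess_config, y$preprocess),
    conditions = conds,
    model = build(fcn_config, y$model),
    train = build(train_config, y$train),
    n_splits = y$n_splits %||% 10L,
    overlay = utils::modifyList(list(window_size = 64L, stride = 16L,
                                     threshold = "youden"),
                                y$overlay %||% list()))
}

#' Write an experiment configuration to YAML
#'
#' @param config An `experiment_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (is.list(v)) strip(v) else v)
  }
  y <- strip(config)
  y$conditions <- lapply(config$conditions, function(cc)
    list(freq_frac = cc$freq_frac, kurtosis_cutoff = cc$kurtosis_cutoff))
  yaml::write_yaml(y, path)
  invisible(path)
}

pipeline_log <- function(log_path, stage, ...) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, paste0(...))
  message(line)
  cat(line, "\n", file = log_path, append = TRUE)
}

#' Run the full tissue-to-inference pipeline
#'
#' Executes simulate, preprocess, qc, train (condition sweep), evaluate
#' and segment from one configuration, writing every stage's artifact
#' under `config$out_dir`:
#' `dataset/` (phantom TIFFs + manifest), `qc_report.csv` (per-condition
#' exclusion counts), `condition_results.csv` (per-condition validation
#' accuracy/AUC mean and sd), `test_metrics.json` (per-model and ensemble
#' test metrics), `overlay_*.tif` + `overlay_iou.json` (boundary-mosaic
#' segmentation), and `run.log`. Stages communicate only via these file
#' artifacts plus returned objects; every stage derives its RNG stream
#' from the master seed and its stage name.
#'
#' The held-out evaluation set is a phantom boundary mosaic: windows
#' extracted from its normal and tumor flanks form the test images
#' (strongly labeled by the generator's reference mask), and the mosaic
#' itself is segmented by the best model.
#'
#' @param config An [experiment_config()].
#' @param verbose Log per-epoch training progress.
#' @return List with the per-stage results (`manifest`, `qc`,
#'   `conditions`, `evaluation`, `iou`, `artifacts`).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  seed <- config$seed

  pipeline_log(log_path, "simulate", "seed ", derive_seed(seed, "simulate"))
  ds <- config$dataset
  ds$seed <- derive_seed(seed, "simulate")
  manifest <- generate_dataset(ds, config$phantom,
                               file.path(out, "dataset"), overwrite = TRUE)

  pipeline_log(log_path, "preprocess", nrow(manifest), " images")
  images <- load_manifest_images(manifest, root = file.path(out, "dataset"),
                                 config = config$preprocess)

  pipeline_log(log_path, "qc", length(config$conditions), " conditions")
  sweep <- condition_sweep(images, config$conditions,
                           ids = manifest_image_ids(manifest))
  write.csv(sweep, file.path(out, "qc_report.csv"), row.names = FALSE)

  pipeline_log(log_path, "train", "seed ", derive_seed(seed, "train"))
  experiment <- run_condition_experiment(
    images, manifest, config$conditions, config$n_splits,
    model_config = config$model, config = config$train,
    seed = derive_seed(seed, "train"), verbose = verbose)
  write.csv(as.data.frame(experiment), file.path(out, "condition_results.csv"),
            row.names = FALSE)
  best_cond <- experiment$condition[experiment$best]
  best_fits <- attr(experiment, "fits")[[best_cond]]
  pipeline_log(log_path, "train", "best condition ", best_cond)

  pipeline_log(log_path, "evaluate", "seed ", derive_seed(seed, "evaluate"))
  ph <- config$phantom
  ph$height <- max(ph$height, 2L * config$overlay$window_size)
  ph$width <- max(ph$width, 4L * config$overlay$window_size)
  mosaic <- render_boundary_mosaic(ph, seed = derive_seed(seed, "evaluate"),
                                   case_id = "test01")
  test <- mosaic_test_windows(mosaic, config$overlay$window_size,
                              config$preprocess)
  evaluation <- evaluate_ensemble(best_fits, test$images, test$labels)
  jsonlite::write_json(
    list(best_condition = best_cond,
         per_model = evaluation$per_model,
         summary = lapply(evaluation$summary, as.list)),
    file.path(out, "test_metrics.json"), auto_unbox = TRUE, digits = NA)

  pipeline_log(log_path, "segment", "window ", config$overlay$window_size,
               " stride ", config$overlay$stride)
  best_i <- which.max(evaluation$per_model$auc)
  threshold <- if (identical(config$overlay$threshold, "youden"))
    evaluation$per_model$threshold[best_i] else config$overlay$threshold
  pp_mosaic <- preprocess_image(mosaic, config$preprocess)
  smap <- sliding_window_scores(pp_mosaic, best_fits[[best_i]],
                                config$overlay$window_size,
                                config$overlay$stride)
  pred_mask <- binarize_overlay(smap, threshold)
  ref <- mosaic$reference_mask
  ref[pred_mask == 0L] <- 0L   # uncovered pixels excluded from scoring
  iou <- jaccard_per_class(pred_mask, ref)
  paths <- write_overlay(file.path(out, "overlay"), smap$mean_score,
                         pred_mask)
  jsonlite::write_json(list(iou_normal = iou$iou_normal,
                            iou_tumor = iou$iou_tumor,
                            threshold = threshold),
                       file.path(out, "overlay_iou.json"),
                       auto_unbox = TRUE, digits = NA)

  artifacts <- c(manifest = file.path(out, "dataset", "manifest.csv"),
                 qc = file.path(out, "qc_report.csv"),
                 conditions = file.path(out, "condition_results.csv"),
                 metrics = file.path(out, "test_metrics.json"),
                 iou = file.path(out, "overlay_iou.json"), paths)
  pipeline_log(log_path, "done", length(artifacts), " artifacts")
  list(manifest = manifest, qc = sweep, conditions = experiment,
       evaluation = evaluation, iou = iou, artifacts = artifacts)
}

# Extract strongly labeled test windows from the flanks of a boundary
# mosaic: windows whose reference mask is entirely one tissue class.
mosaic_test_windows <- function(mosaic, window_size,
                                pp_config = preprocess_config(),
                                max_per_class = 16L) {
  pp <- preprocess_image(mosaic, pp_config)
  m <- pp$pixels / 255
  ref <- mosaic$reference_mask
  # the reference mask lives on the acquisition grid; mosaics must already
  # be at the target pixel size for pixelwise comparison
  stopifnot(identical(dim(m), dim(ref)))
  H <- nrow(m); W <- ncol(m)
  rows <- seq(1L, H - window_size + 1L, by = window_size)
  cols <- seq(1L, W - window_size + 1L, by = window_size %/% 2L)
  images <- list(); labels <- numeric(0)
  for (i in rows) for (j in cols) {
    ri <- i:(i + window_size - 1L); rj <- j:(j + window_size - 1L)
    cls <- unique(as.vector(ref[ri, rj]))
    if (length(cls) == 1 && cls %in% c(1L, 2L)) {
      images[[length(images) + 1L]] <- m[ri, rj]
      labels <- c(labels, as.numeric(cls == 2L))
    }
  }
  keep <- c(utils::head(which(labels == 0), max_per_class),
            utils::head(which(labels == 1), max_per_class))
  list(images = images[keep], labels = labels[keep])
}
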