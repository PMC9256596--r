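cohort_manifest <- function(n_neg = 4, n_pos = 15, imgs = 3) {
  rows <- expand.grid(img = seq_len(imgs),
                      case_id = c(sprintf("e%02d", seq_len(n_neg)),
                                  sprintf("g%02d", seq_len(n_pos))),
                      stringsAsFactors = FALSE)
  validate_manifest(data.frame(
    image_path = sprintf("%s_%d.tif", rows$case_id, rows$img),
    case_id = rows$case_id,
    diagnosis = ifelse(grepl("^e", rows$case_id), "epilepsy", "glioma"),
    split_role = "train", stringsAsFactors = FALSE))
}

test_that("Monte-Carlo splits are case-level with fixed 1+4 validation folds", {
  mf <- cohort_manifest()
  splits <- make_mc_splits(mf, n_splits = 10, seed = 5)
  expect_length(splits, 10)
  for (sp in splits) {
    expect_length(intersect(sp$train_case_ids, sp$val_case_ids), 0)
    neg <- grepl("^e", sp$val_case_ids)
    expect_equal(sum(neg), 1)
    expect_equal(sum(!neg), 4)
    # every case is somewhere, none in both folds
    expect_setequal(c(sp$train_case_ids, sp$val_case_ids),
                    unique(mf$case_id))
  }
  expect_identical(make_mc_splits(mf, 10, seed = 5), splits)
  expect_false(identical(make_mc_splits(mf, 10, seed = 6), splits))

  # with a single negative case the training fold would lose its negatives
  expect_error(make_mc_splits(cohort_manifest(n_neg = 1), 3, 1),
               class = "thgqc_value_error")
})

test_that("identity augmentation returns the input; brightness clips", {
  id_cfg <- train_config(contrast_range = c(1, 1),
                         brightness_range = c(0, 0),
                         rotation_range = c(0, 0))
  withr::with_seed(1, img <- matrix(runif(32 * 32), 32))
  expect_identical(augment_image(img, id_cfg), img)

  bright <- train_config(contrast_range = c(1, 1),
                         brightness_range = c(0.5, 0.5),
                         rotation_range = c(0, 0))
  out <- augment_image(matrix(0.8, 16, 16), bright)
  expect_true(all(out == 1))
})

test_that("90-degree rotation matches the index-permutation oracle", {
  withr::with_seed(2, m <- matrix(runif(12 * 12), 12))
  got <- rotate_reflect(m, 90)
  # independent oracle by explicit index arithmetic
  oracle <- matrix(0, 12, 12)
  for (i in 1:12) for (j in 1:12) oracle[13 - j, i] <- m[i, j]
  expect_equal(got, oracle)
  expect_equal(rotate_reflect(rotate_reflect(m, 180), 180), m)
  # arbitrary-angle rotation stays in range and shape
  r <- rotate_reflect(m, 33.3)
  expect_equal(dim(r), dim(m))
  expect_true(all(r >= min(m) - 1e-12 & r <= max(m) + 1e-12))
})

test_that("epoch streams balance classes exactly and pad per batch", {
  withr::with_seed(3, {
    imgs <- c(lapply(1:10, function(i) matrix(runif(24 * 24), 24)),
              lapply(1:90, function(i) matrix(runif(24 * 24), 24)))
  })
  labels <- c(rep(0, 10), rep(1, 90))
  cfg <- train_config(batch_size = 32L)
  stream <- withr::with_seed(4, make_epoch_stream(imgs, labels, cfg))
  ys <- unlist(lapply(stream, `[[`, "y"))
  expect_length(ys, 180)
  expect_equal(sum(ys == 0), 90)
  expect_equal(sum(ys == 1), 90)

  # mixed sizes pad to the per-batch maximum
  mix <- list(matrix(0.5, 64, 64), matrix(0.5, 100, 80))
  st2 <- withr::with_seed(5, make_epoch_stream(mix, c(0, 1), cfg))
  dims <- vapply(st2[[1]]$x, dim, integer(2))
  expect_true(all(dims[1, ] == 100) && all(dims[2, ] == 80))

  # successive epochs draw fresh orders/augmentations
  s1 <- make_epoch_stream(imgs, labels, cfg)
  s2 <- make_epoch_stream(imgs, labels, cfg)
  expect_false(identical(lapply(s1, `[[`, "y"), lapply(s2, `[[`, "y")) &&
                 identical(s1[[1]]$x[[1]], s2[[1]]$x[[1]]))

  expect_error(make_epoch_stream(imgs[1:5], rep(1, 5), cfg),
               class = "thgqc_value_error")
})

test_that("learning rate drops by the plateau factor and early stopping fires", {
  # a model that cannot learn (constant inputs, vanishing lr) so the
  # validation loss never improves: plateaus at epochs 6 and 11, stop at 11
  cfg_model <- tiny_fcn_config()
  model <- build_fcn(cfg_model, seed = 1)
  imgs <- lapply(1:4, function(i) matrix(0.5, 8, 8))
  labels <- c(0, 1, 0, 1)
  tc <- train_config(initial_lr = 1e-12, max_epochs = 50L,
                     plateau_patience = 5L, early_stop_patience = 10L,
                     contrast_range = c(1, 1), brightness_range = c(0, 0),
                     rotation_range = c(0, 0))
  fit <- train_fcn(model, imgs, labels, imgs, labels, tc, seed = 2)
  h <- fit$history
  # early stopping fires exactly early_stop_patience epochs after the best
  expect_equal(nrow(h), fit$best_epoch + 10)
  # every learning rate is the initial one times a power of the plateau
  # factor, starting unreduced and never increasing
  k <- round(log(h$lr / 1e-12) / log(0.2))
  expect_equal(h$lr, 1e-12 * 0.2^k, tolerance = 1e-10)
  expect_equal(k[1], 0)
  expect_true(all(diff(k) >= 0))
  # after the last improvement, plateaus at 5 and 10 epochs give one lr
  # reduction that affects later epochs plus one at the stopping epoch
  expect_equal(k[nrow(h)], k[fit$best_epoch] + 1)
  # schedule arithmetic: two plateau reductions compose multiplicatively
  expect_equal(1e-4 * 0.2^2, 4e-6)
})

test_that("the checkpoint is the epoch with minimum validation loss", {
  cfg_model <- tiny_fcn_config()
  model <- build_fcn(cfg_model, seed = 3)
  withr::with_seed(6, {
    imgs <- lapply(1:8, function(i) matrix(runif(16 * 16), 16))
  })
  labels <- rep(c(0, 1), 4)
  tc <- train_config(initial_lr = 0.01, max_epochs = 6L,
                     early_stop_patience = 6L)
  fit <- train_fcn(model, imgs, labels, imgs, labels, tc, seed = 7)
  expect_equal(fit$val_loss, min(fit$history$val_loss))
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))
  expect_error(train_fcn(model, list(), numeric(0), imgs, labels, tc),
               class = "thgqc_value_error")
})

test_that("training is reproducible from (data, seed)", {
  cfg_model <- tiny_fcn_config()
  withr::with_seed(8, imgs <- lapply(1:6, function(i) matrix(runif(16 * 16), 16)))
  labels <- rep(c(0, 1), 3)
  tc <- train_config(initial_lr = 0.01, max_epochs = 3L,
                     early_stop_patience = 3L)
  f1 <- train_fcn(build_fcn(cfg_model, seed = 4), imgs, labels, imgs, labels,
                  tc, seed = 11)
  f2 <- train_fcn(build_fcn(cfg_model, seed = 4), imgs, labels, imgs, labels,
                  tc, seed = 11)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$blocks[[1]]$W, f2$model$blocks[[1]]$W)
})
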