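#' Configuration of the fully-convolutional classifier
#'
#' Describes the six-block fully-convolutional network (FCN) used for binary
#' glioma vs. non-tumor classification of THG images. The first four blocks
#' are 5x5 convolution + batch normalization + ReLU + 2x2 max pooling with
#' 32, 64, 128 and 256 channels; the fifth block is a 1x1 convolution with
#' 64 channels (plus batch normalization and ReLU); the sixth block is a 1x1
#' convolution with a single channel followed by global average pooling and
#' a sigmoid. Because there are no dense layers, the model accepts any input
#' of at least `2^n_blocks` pixels per side (16 for the default four pooled
#' blocks).
#'
#' @param block_channels Integer vector of channel counts for the pooled
#'   convolution blocks.
#' @param conv_kernel Odd kernel size of the pooled blocks' convolutions.
#' @param pool Pooling factor (fixed 2x2 max pooling).
#' @param head_channels Channels of the 1x1 penultimate block.
#' @param l2_factor L2 penalty factor applied to convolution kernels: the
#'   loss adds `l2_factor * sum(W^2)` per kernel.
#' @param input_channels Number of image channels (1 for THG intensity).
#' @param bn_momentum Momentum of the batch-normalization running statistics
#'   (running <- momentum * running + (1 - momentum) * batch).
#' @param bn_eps Batch-normalization variance floor.
#' @param precision Convolution arithmetic: `"single"` (float32 GEMM, the
#'   usual deep-learning arithmetic, about twice as fast on one core) or
#'   `"double"` (for exact finite-difference gradient verification).
#' @return An object of class `fcn_config`.
#' @export
fcn_config <- function(block_channels = c(32L, 64L, 128L, 256L),
                       conv_kernel = 5L, pool = 2L, head_channels = 64L,
                       l2_factor = 0.01, input_channels = 1L,
                       bn_momentum = 0.9, bn_eps = 1e-3,
                       precision = c("single", "double")) {
  precision <- match.arg(precision)
  stopifnot(length(block_channels) >= 1, all(block_channels > 0),
            conv_kernel %% 2 == 1, pool == 2L, head_channels > 0,
            l2_factor >= 0, input_channels >= 1,
            bn_momentum > 0, bn_momentum < 1, bn_eps > 0)
  structure(list(block_channels = as.integer(block_channels),
                 conv_kernel = as.integer(conv_kernel),
                 pool = as.integer(pool),
                 head_channels = as.integer(head_channels),
                 l2_factor = l2_factor,
                 input_channels = as.integer(input_channels),
                 bn_momentum = bn_momentum, bn_eps = bn_eps,
                 precision = precision),
            class = "fcn_config")
}

#' Minimum input side length accepted by a model or configuration
#'
#' Each pooled block halves the spatial dimensions, so an `n`-block model
#' needs at least `2^n` pixels per side.
#'
#' @param x An `fcn_config` or `thg_fcn` object.
#' @return Integer minimum side length in pixels.
#' @export
fcn_min_input <- function(x) {
  cfg <- if (inherits(x, "thg_fcn")) x$config else x
  stopifnot(inherits(cfg, "fcn_config"))
  as.integer(cfg$pool^length(cfg$block_channels))
}

he_uniform <- function(fan_in, n) {
  limit <- sqrt(6 / fan_in)
  runif(n, -limit, limit)
}

new_conv <- function(k, cin, cout) {
  list(k = as.integer(k), cin = as.integer(cin), cout = as.integer(cout),
       W = matrix(he_uniform(k * k * cin, k * k * cin * cout),
                  k * k * cin, cout),
       b = numeric(cout))
}

new_bn <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c))
}

#' Build the fully-convolutional classifier
#'
#' Instantiates the FCN with He-uniform initialized convolution kernels,
#' zero biases and identity batch normalization. Two builds with the same
#' seed produce identical initial weights.
#'
#' @param config An [fcn_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `thg_fcn` with elements `config`, `blocks`
#'   (pooled conv blocks, each with conv + batch-norm parameters), `head`
#'   (1x1 block) and `out` (final 1x1 convolution).
#' @export
build_fcn <- function(config = fcn_config(), seed = 1L) {
  stopifnot(inherits(config, "fcn_config"))
  with_seed(seed, function() {
    cins <- c(config$input_channels,
              config$block_channels[-length(config$block_channels)])
    blocks <- vector("list", length(config$block_channels))
    for (i in seq_along(blocks)) {
      blocks[[i]] <- c(new_conv(config$conv_kernel, cins[i],
                                config$block_channels[i]),
                       new_bn(config$block_channels[i]))
    }
    last <- config$block_channels[length(config$block_channels)]
    head <- c(new_conv(1L, last, config$head_channels),
              new_bn(config$head_channels))
    out <- new_conv(1L, config$head_channels, 1L)
    structure(list(config = config, blocks = blocks, head = head, out = out,
                   seed = as.integer(seed)),
              class = "thg_fcn")
  })
}

#' Count trainable convolution parameters
#'
#' Sums kernel weights and biases over all convolutional layers. With the
#' default configuration (blocks 32/64/128/256 with 5x5 kernels, a 64-channel
#' 1x1 head and a single-channel 1x1 output) this is 1,092,993. Batch
#' normalization parameters are reported separately by [summary.thg_fcn()].
#'
#' @param model A `thg_fcn`.
#' @return Integer number of convolution weights plus biases.
#' @export
fcn_parameter_count <- function(model) {
  stopifnot(inherits(model, "thg_fcn"))
  layers <- c(model$blocks, list(model$head), list(model$out))
  sum(vapply(layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

bn_param_count <- function(model) {
  layers <- c(model$blocks, list(model$head))
  sum(vapply(layers, function(l) 2L * length(l$gamma), integer(1)))
}

#' @export
print.thg_fcn <- function(x, ...) {
  cfg <- x$config
  cat("THG fully-convolutional binary classifier\n")
  cat(sprintf("  pooled blocks: %s (kernel %dx%d, 2x2 max pool)\n",
              paste(cfg$block_channels, collapse = "-"),
              cfg$conv_kernel, cfg$conv_kernel))
  cat(sprintf("  head: 1x1 conv %d ch; output: 1x1 conv + GAP + sigmoid\n",
              cfg$head_channels))
  cat(sprintf("  conv parameters: %s (+ %s batch-norm)\n",
              format(fcn_parameter_count(x), big.mark = ","),
              format(bn_param_count(x), big.mark = ",")))
  cat(sprintf("  minimum input: %dx%d px; L2 factor %g\n",
              fcn_min_input(x), fcn_min_input(x), cfg$l2_factor))
  invisible(x)
}

#' @export
summary.thg_fcn <- function(object, ...) {
  print(object)
  cat("\nLayers:\n")
  cins <- c(object$config$input_channels,
            object$config$block_channels[-length(object$config$block_channels)])
  for (i in seq_along(object$blocks)) {
    l <- object$blocks[[i]]
    cat(sprintf("  block %d: conv %dx%dx%d->%d (%d par), BN, ReLU, maxpool\n",
                i, l$k, l$k, l$cin, l$cout, length(l$W) + length(l$b)))
  }
  cat(sprintf("  block %d: conv 1x1x%d->%d (%d par), BN, ReLU\n",
              length(object$blocks) + 1L, object$head$cin, object$head$cout,
              length(object$head$W) + length(object$head$b)))
  cat(sprintf("  block %d: conv 1x1x%d->1 (%d par), global average pool, sigmoid\n",
              length(object$blocks) + 2L, object$out$cin,
              length(object$out$W) + length(object$out$b)))
  invisible(object)
}

as_input_cube <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3)
  x
}

# Inference-mode forward pass for one image (matrix or H x W x C array of
# intensities in [0,1]); batch normalization uses running statistics, so the
# result is a pure function of (model, image).
fcn_forward_infer <- function(model, x) {
  cfg <- model$config
  single <- identical(cfg$precision %||% "single", "single")
  a <- as_input_cube(x)
  if (min(dim(a)[1:2]) < fcn_min_input(model)) {
    stop_thgqc("input ", dim(a)[1], "x", dim(a)[2],
               " below the model minimum of ", fcn_min_input(model),
               "x", fcn_min_input(model), " px", class = "thgqc_size_error")
  }
  for (bl in model$blocks) {
    a <- cpp_conv2d_fwd(a, bl$W, bl$b, bl$k, single)
    a <- cpp_bn_relu_fwd(a, bl$gamma, bl$beta, bl$run_mean,
                         1 / sqrt(bl$run_var + cfg$bn_eps))
    a <- cpp_maxpool2_fwd(a)$y
  }
  a <- cpp_conv2d_fwd(a, model$head$W, model$head$b, 1L, single)
  a <- cpp_bn_relu_fwd(a, model$head$gamma, model$head$beta,
                       model$head$run_mean,
                       1 / sqrt(model$head$run_var + cfg$bn_eps))
  a <- cpp_conv2d_fwd(a, model$out$W, model$out$b, 1L, single)
  logit <- mean(a)
  list(score = plogis(logit), logit = logit, logit_map = a[, , 1])
}

#' Predict tumor scores for images
#'
#' Runs an unpadded per-image forward pass in inference mode (batch
#' normalization uses running statistics), returning one sigmoid score per
#' image. Any input of at least the model's minimum side length is accepted;
#' images in one call may have different sizes.
#'
#' @param object A `thg_fcn`.
#' @param newdata A numeric matrix with values in \[0,1\], a list of such
#'   matrices, or [image_record()] objects (rescaled by their bit depth).
#' @param ... Unused.
#' @return Numeric vector of scores in \[0,1\].
#' @export
predict.thg_fcn <- function(object, newdata, ...) {
  imgs <- normalize_prediction_inputs(newdata)
  vapply(imgs, function(m) fcn_forward_infer(object, m)$score, numeric(1))
}

normalize_prediction_inputs <- function(newdata) {
  as_unit_matrix <- function(x) {
    if (inherits(x, "image_record")) {
      m <- x$pixels / (2^x$bit_depth - 1)
    } else if (is.matrix(x)) {
      m <- x
    } else {
      stop_thgqc("predict inputs must be matrices or image records",
                 class = "thgqc_value_error")
    }
    if (anyNA(m) || min(m) < 0 || max(m) > 1) {
      stop_thgqc("prediction inputs must be finite and scaled to [0,1]",
                 class = "thgqc_value_error")
    }
    m
  }
  if (is.matrix(newdata) || inherits(newdata, "image_record")) {
    list(as_unit_matrix(newdata))
  } else {
    lapply(newdata, as_unit_matrix)
  }
}

## ---- training-mode forward / backward over a padded batch ----

# xs: list of H x W matrices, all the same size (already padded); returns
# scores plus the caches needed for backpropagation. Batch-norm statistics
# are computed over batch and spatial dimensions per channel and the running
# statistics in `model` are updated (the updated model is returned).
fcn_forward_train <- function(model, xs) {
  cfg <- model$config
  single <- identical(cfg$precision %||% "single", "single")
  eps <- cfg$bn_eps
  mom <- cfg$bn_momentum
  n <- length(xs)
  acts <- lapply(xs, as_input_cube)
  caches <- list()
  layer_fwd <- function(layer, acts, pooled) {
    conv_out <- lapply(acts, function(a)
      cpp_conv2d_fwd(a, layer$W, layer$b, layer$k, single))
    d <- dim(conv_out[[1]])
    m <- d[1] * d[2]
    sums <- 0; sq <- 0
    for (a in conv_out) {
      st <- cpp_bn_stats(a)
      sums <- sums + st$sum
      sq <- sq + st$sumsq
    }
    total <- m * n
    mu <- as.numeric(sums / total)
    va <- pmax(as.numeric(sq / total) - mu^2, 0)
    inv_sd <- 1 / sqrt(va + eps)
    act <- lapply(conv_out, function(a)
      cpp_bn_relu_fwd(a, layer$gamma, layer$beta, mu, inv_sd))
    pool_idx <- NULL
    if (pooled) {
      pooled_out <- lapply(act, cpp_maxpool2_fwd)
      act <- lapply(pooled_out, `[[`, "y")
      pool_idx <- lapply(pooled_out, `[[`, "idx")
    }
    list(out = act,
         cache = list(input = acts, conv_out = conv_out, mu = mu, va = va,
                      inv_sd = inv_sd, dim = d, pool_idx = pool_idx),
         stats = list(mu = mu, va = va))
  }
  for (i in seq_along(model$blocks)) {
    res <- layer_fwd(model$blocks[[i]], acts, pooled = TRUE)
    acts <- res$out
    caches[[i]] <- res$cache
    model$blocks[[i]]$run_mean <- mom * model$blocks[[i]]$run_mean +
      (1 - mom) * res$stats$mu
    model$blocks[[i]]$run_var <- mom * model$blocks[[i]]$run_var +
      (1 - mom) * res$stats$va
  }
  res <- layer_fwd(model$head, acts, pooled = FALSE)
  acts <- res$out
  head_cache <- res$cache
  model$head$run_mean <- mom * model$head$run_mean + (1 - mom) * res$stats$mu
  model$head$run_var <- mom * model$head$run_var + (1 - mom) * res$stats$va
  out_in <- acts
  logit_maps <- lapply(acts, function(a)
    cpp_conv2d_fwd(a, model$out$W, model$out$b, 1L, single))
  logits <- vapply(logit_maps, mean, numeric(1))
  list(model = model, scores = plogis(logits), logits = logits,
       caches = caches, head_cache = head_cache, out_in = out_in,
       map_dim = dim(logit_maps[[1]]))
}

# Batch-norm + ReLU backward through one layer's cache. dys: list of
# gradient cubes w.r.t. the post-ReLU activation (pre-pooling resolution).
bn_relu_conv_bwd <- function(layer, cache, dys, single = TRUE) {
  d <- cache$dim
  m <- d[1] * d[2]
  n <- length(dys)
  total <- m * n
  sum_dy <- 0; sum_dy_xhat <- 0
  for (i in seq_len(n)) {
    s <- cpp_bn_relu_bwd_sums(cache$conv_out[[i]], dys[[i]],
                              layer$gamma, layer$beta,
                              cache$mu, cache$inv_sd)
    sum_dy <- sum_dy + s$sum_dy
    sum_dy_xhat <- sum_dy_xhat + s$sum_dy_xhat
  }
  dW <- 0; db <- 0
  dinput <- vector("list", n)
  for (i in seq_len(n)) {
    dconv <- cpp_bn_relu_bwd_dx(cache$conv_out[[i]], dys[[i]],
                                layer$gamma, layer$beta,
                                cache$mu, cache$inv_sd,
                                sum_dy / total, sum_dy_xhat / total)
    bw <- cpp_conv2d_bwd(cache$input[[i]], layer$W, dconv, layer$k, single)
    dW <- dW + bw$dw
    db <- db + bw$db
    dinput[[i]] <- bw$dx
  }
  list(dW = dW, db = db, dgamma = as.numeric(sum_dy_xhat),
       dbeta = as.numeric(sum_dy), dinput = dinput)
}

# Full backward pass; dlogits: d(loss)/d(logit) per image. Returns gradients
# shaped like the model parameters (L2 penalty gradients NOT included; the
# optimizer adds them so that the penalty acts on kernels only).
fcn_backward <- function(model, fwd, dlogits) {
  single <- identical(model$config$precision %||% "single", "single")
  n <- length(dlogits)
  md <- fwd$map_dim
  m <- md[1] * md[2]
  # global average pooling spreads the logit gradient uniformly
  dmaps <- lapply(dlogits, function(dl) array(dl / m, md))
  dW_out <- 0; db_out <- 0
  d_out_in <- vector("list", n)
  for (i in seq_len(n)) {
    bw <- cpp_conv2d_bwd(fwd$out_in[[i]], model$out$W, dmaps[[i]], 1L, single)
    dW_out <- dW_out + bw$dw
    db_out <- db_out + bw$db
    d_out_in[[i]] <- bw$dx
  }
  grads <- list(out = list(W = dW_out, b = db_out))
  hb <- bn_relu_conv_bwd(model$head, fwd$head_cache, d_out_in, single)
  grads$head <- list(W = hb$dW, b = hb$db, gamma = hb$dgamma, beta = hb$dbeta)
  dys <- hb$dinput
  grads$blocks <- vector("list", length(model$blocks))
  for (i in rev(seq_along(model$blocks))) {
    cache <- fwd$caches[[i]]
    d <- cache$dim
    dpre_pool <- lapply(seq_len(n), function(j)
      cpp_maxpool2_bwd(cache$pool_idx[[j]], dys[[j]], d[1], d[2]))
    bb <- bn_relu_conv_bwd(model$blocks[[i]], cache, dpre_pool, single)
    grads$blocks[[i]] <- list(W = bb$dW, b = bb$db,
                              gamma = bb$dgamma, beta = bb$dbeta)
    dys <- bb$dinput
  }
  grads
}

# Binary cross-entropy averaged over the batch plus the L2 kernel penalty.
fcn_loss <- function(model, scores, labels) {
  eps <- 1e-12
  p <- pmin(pmax(scores, eps), 1 - eps)
  bce <- -mean(labels * log(p) + (1 - labels) * log(1 - p))
  bce + fcn_l2_penalty(model)
}

fcn_l2_penalty <- function(model) {
  layers <- c(model$blocks, list(model$head), list(model$out))
  model$config$l2_factor * sum(vapply(layers, function(l) sum(l$W^2),
                                      numeric(1)))
}

# One SGD-with-momentum step. `state` carries velocity buffers; gradients of
# the L2 penalty (2 * l2 * W) are added to kernel gradients here.
fcn_sgd_step <- function(model, grads, state, lr, momentum = 0.9) {
  upd <- function(par, g, vel) {
    v <- momentum * vel - lr * g
    list(par = par + v, vel = v)
  }
  l2 <- model$config$l2_factor
  apply_layer <- function(layer, g, st, name) {
    fields <- intersect(names(g), c("W", "b", "gamma", "beta"))
    for (f in fields) {
      gr <- g[[f]]
      if (f == "W") gr <- gr + 2 * l2 * layer$W
      key <- paste0(name, ".", f)
      vel <- state[[key]] %||% 0
      r <- upd(layer[[f]], gr, vel)
      layer[[f]] <- r$par
      state[[key]] <<- r$vel
    }
    layer
  }
  for (i in seq_along(model$blocks)) {
    model$blocks[[i]] <- apply_layer(model$blocks[[i]], grads$blocks[[i]],
                                     state, paste0("block", i))
  }
  model$head <- apply_layer(model$head, grads$head, state, "head")
  model$out <- apply_layer(model$out, grads$out, state, "out")
  list(model = model, state = state)
}

#' Save and load model checkpoints
#'
#' A checkpoint is a single-file container holding the full parameter set
#' with the architecture configuration embedded, so a reloaded model is
#' usable without any side information.
#'
#' @param model A `thg_fcn` or `thg_fcn_fit`.
#' @param path Checkpoint file path.
#' @return `save_fcn` returns `path` invisibly; `load_fcn` returns the
#'   restored object.
#' @export
save_fcn <- function(model, path) {
  stopifnot(inherits(model, c("thg_fcn", "thg_fcn_fit")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_fcn
#' @export
load_fcn <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, c("thg_fcn", "thg_fcn_fit"))) {
    stop_thgqc("not a classifier checkpoint: ", path,
               class = "thgqc_format_error")
  }
  obj
}
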