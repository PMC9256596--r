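test_that("the default architecture has the exact convolution parameter count", {
  model <- build_fcn(seed = 1)
  # layer-arithmetic oracle: sum over conv layers of k^2 * c_in * c_out + c_out
  dims <- rbind(c(5, 1, 32), c(5, 32, 64), c(5, 64, 128), c(5, 128, 256),
                c(1, 256, 64), c(1, 64, 1))
  oracle <- sum(apply(dims, 1, function(d) d[1]^2 * d[2] * d[3] + d[3]))
  expect_equal(fcn_parameter_count(model), oracle)
  expect_equal(oracle, 832 + 51264 + 204928 + 819456 + 16448 + 65)
})

test_that("weight initialization is seeded and deterministic", {
  a <- build_fcn(seed = 99)
  b <- build_fcn(seed = 99)
  expect_identical(a$blocks, b$blocks)
  expect_identical(a$head, b$head)
  expect_identical(a$out, b$out)
  c <- build_fcn(seed = 100)
  expect_false(identical(a$blocks[[1]]$W, c$blocks[[1]]$W))
})

test_that("minimum input side follows the pooling arithmetic", {
  expect_equal(fcn_min_input(fcn_config()), 16)
  cfg3 <- fcn_config(block_channels = c(8L, 16L, 32L))
  expect_equal(fcn_min_input(cfg3), 8)
  model <- build_fcn(seed = 1)
  expect_error(predict(model, matrix(0.5, 15, 15)),
               class = "thgqc_size_error")
})

test_that("one model accepts dynamic input sizes and emits sigmoid scores", {
  model <- build_fcn(seed = 2)
  withr::with_seed(1, {
    imgs <- list(matrix(runif(64 * 64), 64),
                 matrix(runif(256 * 256), 256),
                 matrix(runif(100 * 180), 100))
  })
  s <- predict(model, imgs)
  expect_length(s, 3)
  expect_true(all(s > 0 & s < 1))
})

test_that("inference is per-image deterministic and batch-composition invariant", {
  model <- build_fcn(seed = 3)
  withr::with_seed(2, img <- matrix(runif(48 * 48), 48))
  s <- predict(model, list(img, img))
  expect_identical(s[1], s[2])
  other <- matrix(0.2, 48, 48)
  expect_identical(predict(model, list(img, other))[1], s[1])
})

test_that("for a constant input the interior spatial logits coincide", {
  # zero 'same' padding perturbs border logits, so the translation-symmetry
  # argument applies to logit-map cells whose receptive field avoids the
  # image border (the map is 16x downsampled; the receptive field spans
  # about 65 input px, so a 3-cell margin suffices at 256 px input)
  model <- build_fcn(seed = 4)
  fw <- thgqc:::fcn_forward_infer(model, matrix(0.5, 256, 256))
  interior <- fw$logit_map[4:13, 4:13]
  expect_lt(diff(range(interior)), 1e-5)
  # the score is the sigmoid of the pooled (mean) logit by construction,
  # so it tracks any single interior logit up to the border contribution
  expect_equal(fw$score, plogis(mean(fw$logit_map)))
  expect_equal(fw$score, plogis(interior[1, 1]), tolerance = 0.05)
})

test_that("backpropagation matches central finite differences (double path)", {
  cfg <- tiny_fcn_config()
  model <- build_fcn(cfg, seed = 7)
  withr::with_seed(1, xs <- list(matrix(runif(12 * 12), 12),
                                 matrix(runif(12 * 12), 12)))
  y <- c(1, 0)
  lossfun <- function(m) {
    fwd <- thgqc:::fcn_forward_train(m, xs)
    thgqc:::fcn_loss(m, fwd$scores, y)
  }
  fwd <- thgqc:::fcn_forward_train(model, xs)
  grads <- thgqc:::fcn_backward(model, fwd, (fwd$scores - y) / length(y))
  l2 <- cfg$l2_factor
  eps <- 1e-6
  check <- function(get, set, analytic) {
    idx <- unique(pmin(c(1, 7, length(get(model))), length(get(model))))
    for (i in idx) {
      up <- model; v <- get(up); v[i] <- v[i] + eps; up <- set(up, v)
      dn <- model; v <- get(dn); v[i] <- v[i] - eps; dn <- set(dn, v)
      num <- (lossfun(up) - lossfun(dn)) / (2 * eps)
      expect_equal(analytic[i], num, tolerance = 1e-5)
    }
  }
  check(function(m) m$blocks[[1]]$W,
        function(m, v) { m$blocks[[1]]$W[] <- v; m },
        grads$blocks[[1]]$W + 2 * l2 * model$blocks[[1]]$W)
  check(function(m) m$blocks[[2]]$gamma,
        function(m, v) { m$blocks[[2]]$gamma <- v; m },
        grads$blocks[[2]]$gamma)
  check(function(m) m$head$W,
        function(m, v) { m$head$W[] <- v; m },
        grads$head$W + 2 * l2 * model$head$W)
  check(function(m) m$out$b,
        function(m, v) { m$out$b <- v; m },
        grads$out$b)
})

test_that("single- and double-precision forward passes agree", {
  ms <- build_fcn(fcn_config(), seed = 5)
  md <- build_fcn(fcn_config(precision = "double"), seed = 5)
  withr::with_seed(3, img <- matrix(runif(64 * 64), 64))
  expect_equal(predict(ms, img), predict(md, img), tolerance = 1e-5)
})

test_that("convolution matches a direct R reference on a small fixture", {
  # independent oracle: plain quadruple-loop 'same' convolution
  ref_conv <- function(x, Warr, b) {
    k <- dim(Warr)[1]; cin <- dim(Warr)[3]; cout <- dim(Warr)[4]
    H <- dim(x)[1]; W2 <- dim(x)[2]
    pad <- (k - 1) / 2
    out <- array(0, c(H, W2, cout))
    for (co in seq_len(cout)) {
      acc <- matrix(b[co], H, W2)
      for (ci in seq_len(cin)) for (dj in seq_len(k)) for (di in seq_len(k)) {
        w <- Warr[di, dj, ci, co]
        if (w == 0) next
        src <- matrix(0, H, W2)
        ii <- seq_len(H) + di - 1 - pad
        jj <- seq_len(W2) + dj - 1 - pad
        ok_i <- ii >= 1 & ii <= H; ok_j <- jj >= 1 & jj <= W2
        src[ok_i, ok_j] <- x[ii[ok_i], jj[ok_j], ci]
        acc <- acc + w * src
      }
      out[, , co] <- acc
    }
    out
  }
  withr::with_seed(8, {
    x <- array(runif(10 * 11 * 2), c(10, 11, 2))
    Warr <- array(rnorm(3 * 3 * 2 * 4, sd = 0.3), c(3, 3, 2, 4))
    b <- rnorm(4)
  })
  wmat <- matrix(Warr, 3 * 3 * 2, 4)
  got <- thgqc:::cpp_conv2d_fwd(x, wmat, b, 3L, FALSE)
  expect_equal(got, ref_conv(x, Warr, b), tolerance = 1e-12)
  got_f <- thgqc:::cpp_conv2d_fwd(x, wmat, b, 3L, TRUE)
  expect_equal(got_f, ref_conv(x, Warr, b), tolerance = 1e-5)
})
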