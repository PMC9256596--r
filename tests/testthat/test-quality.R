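test_that("the spectral tail selects exactly the high-frequency annulus", {
  withr::with_seed(3, m <- matrix(rnorm(64 * 64), 64, 64))
  tail <- power_spectrum_tail(m, 0.2)
  # oracle: enumerate the radial grid directly
  fr <- function(n) { k <- 0:(n - 1); ifelse(k <= n %/% 2, k, k - n) / n }
  r <- sqrt(outer(fr(64)^2, fr(64)^2, `+`)) / 0.5
  expect_equal(tail$n_coefficients, sum(r >= 0.8 & r > 0))
  expect_length(tail$power_values, tail$n_coefficients)
  expect_true(all(tail$power_values >= 0))

  # a pure low-frequency sinusoid has (essentially) no tail power
  x <- outer(seq_len(64), rep(1, 64)) / 64
  sin_img <- sin(2 * pi * 2 * x)       # period 32 px
  tl <- power_spectrum_tail(sin_img, 0.2)
  full_power <- sum(Mod(fft(sin_img - mean(sin_img)))^2)
  expect_lt(sum(tl$power_values) / full_power, 1e-20)

  # constant image: all tail power zero, kurtosis undefined sentinel
  ct <- power_spectrum_tail(matrix(5, 32, 32), 0.2)
  expect_true(all(ct$power_values == 0))
  expect_true(is.nan(tail_statistics(ct)$kurtosis))

  expect_error(power_spectrum_tail(matrix(0, 8, 8), 0.2),
               class = "thgqc_value_error")
  expect_error(power_spectrum_tail(matrix(NaN, 32, 32), 0.2),
               class = "thgqc_value_error")
})

test_that("tail statistics match brute-force standardized moments", {
  # five-number example by direct moment arithmetic
  v <- c(0, 0, 0, 0, 1)
  st <- tail_statistics(v)
  o <- moment_stats(v)
  expect_equal(st$kurtosis, o$kurtosis, tolerance = 1e-12)
  expect_equal(st$skewness, o$skewness, tolerance = 1e-12)
  expect_equal(st$mean, 0.2)
  expect_equal(st$inverse_mean, 5)
  expect_equal(st$coefficient_of_variation, st$std / st$mean)
  expect_equal(st$inverse_std, 1 / st$std)

  # zero variance: sentinel kurtosis/skewness
  z <- tail_statistics(c(1, 1, 1, 1))
  expect_equal(z$mean, 1)
  expect_equal(z$std, 0)
  expect_true(is.nan(z$kurtosis) && is.nan(z$skewness))

  # random fixtures vs the independent e1071 implementation
  for (seed in 1:5) {
    x <- withr::with_seed(seed, rexp(10^sample(2:4, 1)))
    st <- tail_statistics(x)
    expect_equal(st$kurtosis, e1071::kurtosis(x, type = 1) + 3,
                 tolerance = 1e-10)
    expect_equal(st$skewness, e1071::skewness(x, type = 1),
                 tolerance = 1e-10)
  }
  expect_error(tail_statistics(numeric(0)), class = "thgqc_value_error")
})

test_that("tail kurtosis is rotation- and intensity-scale-invariant", {
  withr::with_seed(9, m <- matrix(rexp(48 * 48), 48, 48))
  k0 <- tail_kurtosis(m, 0.2)
  rot90 <- t(m)[ncol(m):1, ]
  # same multiset of tail coefficients; summation order may differ
  expect_equal(tail_kurtosis(rot90, 0.2), k0, tolerance = 1e-12)
  expect_equal(tail_kurtosis(3.7 * m, 0.2), k0, tolerance = 1e-12)
})

test_that("quality conditions exclude by kurtosis cutoff, monotonically", {
  imgs <- withr::with_seed(21, lapply(1:6, function(i)
    render_tissue_image(small_phantom(), "normal", seed = i,
                        contrast = c(1, 1, 1, 0.03, 0.03, 0.03)[i])$image))
  r_none <- apply_quality_condition(imgs, quality_condition(NA, NA))
  expect_equal(attr(r_none, "n_excluded"), 0)

  r10 <- apply_quality_condition(imgs, quality_condition(0.2, 10))
  r5 <- apply_quality_condition(imgs, quality_condition(0.2, 5))
  expect_true(all(r10$id[r10$excluded] %in% r5$id[r5$excluded]))
  expect_true(all(r10$excluded == (r10$kurtosis > 10)))

  expect_error(quality_condition(0.2, NA), class = "thgqc_config_error")
  expect_error(apply_quality_condition(list(), quality_condition(NA, NA)),
               class = "thgqc_value_error")
})

test_that("fixed kurtoses behave exactly at the cutoffs", {
  # synthetic images are overkill here: drive the rule through matrices with
  # known kurtosis by monkey-directly checking the rule on reported values
  imgs <- withr::with_seed(2, lapply(1:3, function(i)
    matrix(rexp(32 * 32), 32, 32)))
  rep10 <- apply_quality_condition(imgs, quality_condition(0.2, 10))
  expect_identical(rep10$excluded, rep10$kurtosis > 10)
  rep5 <- apply_quality_condition(imgs, quality_condition(0.2, 5))
  expect_identical(rep5$excluded, rep5$kurtosis > 5)
  expect_gte(attr(rep5, "n_excluded"), attr(rep10, "n_excluded"))
})

test_that("condition sweep tabulates the seven canonical conditions", {
  imgs <- withr::with_seed(4, lapply(1:8, function(i)
    matrix(rexp(32 * 32), 32, 32)))
  sw <- condition_sweep(imgs)
  expect_equal(nrow(sw), 7)
  expect_equal(sw$n_excluded[1], 0)     # none-none excludes nothing
  for (ff in c(0.4, 0.2, 0.1)) {
    n5 <- sw$n_excluded[sw$freq_frac %in% ff & sw$kurtosis_cutoff %in% 5]
    n10 <- sw$n_excluded[sw$freq_frac %in% ff & sw$kurtosis_cutoff %in% 10]
    expect_gte(n5, n10)
  }
  expect_error(condition_sweep(list()), class = "thgqc_value_error")
})

test_that("stack kurtosis profiles are depth-ordered and normalizable", {
  p <- small_phantom()
  zs <- render_zstack(p, "normal", n_slices = 4L, depth_step_um = 10,
                      seed = 5)
  prof <- stack_kurtosis_profile(zs, 0.2)
  expect_length(prof, 4)
  norm <- stack_kurtosis_profile(zs, 0.2, normalize_to = max(prof))
  expect_true(all(norm <= 1 + 1e-12))
  expect_error(stack_kurtosis_profile(zs, 0.2, normalize_to = 0),
               class = "thgqc_value_error")

  # identical slices give a constant profile
  rec <- render_tissue_image(p, "normal", seed = 1)$image
  same <- zstack(list(
    image_record(rec$pixels, 0.5, 16L, "c", depth_index = 0L),
    image_record(rec$pixels, 0.5, 16L, "c", depth_index = 1L)), 5)
  cp <- stack_kurtosis_profile(same, 0.2)
  expect_equal(cp[1], cp[2])
})
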