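test_that("rendering is a pure function of parameters and seed", {
  p <- small_phantom()
  a <- render_tissue_image(p, "tumor", seed = 42)
  b <- render_tissue_image(p, "tumor", seed = 42)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$cell_mask, b$cell_mask)
  c <- render_tissue_image(p, "tumor", seed = 43)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("zero densities and fiber counts render background plus noise only", {
  p <- small_phantom(cell_density_normal = 0, cell_density_tumor = 1e-9,
                     fiber_count = 0L, noise_sigma = 0, line_sigma = 0,
                     shot_photons = 1e9)
  r <- render_tissue_image(p, "normal", seed = 1)
  expect_equal(r$n_cells, 0)
  expect_false(any(r$cell_mask))
  expect_false(any(r$fiber_mask))
  # essentially noiseless: flat background at the configured level
  expect_lt(diff(range(r$image$pixels)) / 65535, 0.01)
  expect_equal(median(r$image$pixels) / 65535, p$background_level,
               tolerance = 0.01)
})

test_that("unrealistic cell coverage is rejected", {
  expect_error(
    render_tissue_image(small_phantom(cell_density_normal = 100,
                                      cell_density_tumor = 6000),
                        "tumor", seed = 1),
    class = "thgqc_param_error")
})

test_that("rendered cell counts follow the Poisson densities (4x tumor ratio)", {
  # 1 mm^2 field at 1 um/px; small radii so components rarely merge
  p <- phantom_params(height = 1000L, width = 1000L, pixel_size_um = 1,
                      cell_density_normal = 300, cell_density_tumor = 1200,
                      cell_radius_um = c(2, 4), fiber_count = 0L)
  rn <- render_tissue_image(p, "normal", seed = 10)
  rt <- render_tissue_image(p, "tumor", seed = 11)
  expect_lt(abs(rn$n_cells - 300), 3 * sqrt(300))
  expect_lt(abs(rt$n_cells - 1200), 3 * sqrt(1200))
  # oracle: connected components of the mask against the sampled count
  cc_n <- max(EBImage::bwlabel(rn$cell_mask))
  cc_t <- max(EBImage::bwlabel(rt$cell_mask))
  expect_gt(cc_n, 0.9 * rn$n_cells)
  expect_gt(cc_t, 0.85 * rt$n_cells)
  expect_lt(abs(cc_t / cc_n - 4), 4 * (1 / sqrt(300) + 1 / sqrt(1200)) * 4)
})

test_that("tumor phantoms show measurably higher cell density than normal", {
  p <- small_phantom(height = 128L, width = 128L)
  for (seed in 1:5) {
    rn <- render_tissue_image(p, "normal", seed = seed)
    rt <- render_tissue_image(p, "tumor", seed = seed + 100)
    expect_gt(sum(rt$cell_mask), sum(rn$cell_mask))
  }
})

test_that("z-stack contrast decays exponentially with depth", {
  # near-noiseless rendering isolates the attenuation factor
  p <- small_phantom(noise_sigma = 0, line_sigma = 0, shot_photons = 1e9,
                     depth_decay_per_um = 0.05)
  zs <- render_zstack(p, "tumor", n_slices = 5L, depth_step_um = 20,
                      seed = 2)
  sds <- vapply(zs$slices, function(s) sd(as.numeric(s$pixels)), numeric(1))
  for (k in 1:4) {
    expect_equal(sds[k + 1] / sds[1], exp(-0.05 * k * 20), tolerance = 0.02)
  }
  # contrast of the last slice is under 1% of the first
  expect_lt(sds[5] / sds[1], 0.02)
  expect_true(all(diff(sds) < 0))   # SNR strictly decreasing (fixed noise)

  # zero decay: slices share the contrast scale
  p0 <- small_phantom(noise_sigma = 0, line_sigma = 0, shot_photons = 1e9,
                      depth_decay_per_um = 0)
  z0 <- render_zstack(p0, "tumor", n_slices = 3L, seed = 3)
  s0 <- vapply(z0$slices, function(s) sd(as.numeric(s$pixels)), numeric(1))
  expect_lt(diff(range(s0)) / s0[1], 0.05)

  expect_error(phantom_params(depth_decay_per_um = -1),
               class = "thgqc_param_error")
  expect_error(render_zstack(small_phantom(), "normal", n_slices = 1L))
})

test_that("boundary mosaics ramp density left to right with a midpoint mask", {
  p <- phantom_params(height = 300L, width = 1200L, pixel_size_um = 1,
                      cell_density_normal = 300, cell_density_tumor = 1200,
                      cell_radius_um = c(2, 4), fiber_count = 0L)
  mos <- render_boundary_mosaic(p, seed = 6)
  expect_s3_class(mos, "thg_mosaic")
  expect_identical(dim(mos$reference_mask), dim(mos$pixels))
  # symmetric ramp: the class split is half and half
  expect_equal(mean(mos$reference_mask == 1), 0.5)
  expect_equal(mean(mos$reference_mask == 2), 0.5)
  expect_true(all(mos$reference_mask[, 1:600] == 1L))
  expect_true(all(mos$reference_mask[, 601:1200] == 2L))

  # strip densities: leftmost 10% near normal, rightmost near tumor
  w10 <- 120
  left <- max(EBImage::bwlabel(mos$cell_mask[, 1:w10]))
  right <- max(EBImage::bwlabel(mos$cell_mask[, (1200 - w10 + 1):1200]))
  area <- 0.3 * 0.12   # mm^2 per strip
  lam_l <- (300 + 0.05 * 900) * area    # mean ramp density over the strip
  lam_r <- (300 + 0.95 * 900) * area
  expect_lt(abs(left - lam_l), 4 * sqrt(lam_l))
  expect_lt(abs(right - lam_r), 4 * sqrt(lam_r))

  # degenerate ramp: equal endpoint densities give a single-class mask
  pd <- phantom_params(height = 64L, width = 128L,
                       cell_density_normal = 300,
                       cell_density_tumor = 300, fiber_count = 2L)
  md <- render_boundary_mosaic(pd, seed = 7)
  expect_equal(length(unique(as.vector(md$reference_mask))), 1)
})

test_that("dataset generation writes a reproducible cohort-shaped manifest", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  spec <- dataset_spec(n_normal_cases = 4L, n_tumor_cases = 15L,
                       images_per_case = c(2L, 4L), normal_fraction = 0.097,
                       stack_fraction = 0.3, seed = 9L)
  p <- small_phantom(height = 32L, width = 32L)
  m1 <- generate_dataset(spec, p, dir1)
  cases <- unique(m1[, c("case_id", "diagnosis")])
  expect_equal(sum(cases$diagnosis == "epilepsy"), 4)
  expect_equal(sum(cases$diagnosis == "glioma"), 15)
  frac_normal <- mean(m1$label == "normal")
  expect_lt(abs(frac_normal - 0.097), 0.06)
  expect_true(all(file.exists(file.path(dir1, unique(m1$image_path)))))

  # rerun with the same seed: byte-identical manifest
  generate_dataset(spec, p, dir2)
  expect_identical(readLines(file.path(dir1, "manifest.csv")),
                   readLines(file.path(dir2, "manifest.csv")))
  # refuses to clobber without the overwrite flag
  expect_error(generate_dataset(spec, p, dir1), class = "thgqc_exists_error")
  expect_error(dataset_spec(n_normal_cases = 0L), class = "thgqc_param_error")
})
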