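#' Parameters of the THG tissue phantom renderer
#'
#' The phantom emulates the appearance of THG 'shadow contrast' images of
#' brain tissue: a mid-gray neuropil background, bright curvilinear
#' myelinated fibers, and dark circular cell bodies with a dimly visible
#' interior nucleus. Tumor phantoms differ from normal ones only by an
#' elevated cell-body density, which is the separable signal a classifier
#' must learn. Rendering is appearance-level only; no attempt is made to
#' simulate the nonlinear optics of third-harmonic signal generation.
#'
#' The imaging model mimics a laser-scanning detector chain. The noiseless
#' structure is blurred by a Gaussian optical point-spread function
#' (`psf_sigma_px`), attenuated as a whole by the depth contrast factor
#' (signal loss), and detected with Poisson shot noise (`shot_photons`
#' photons at full scale, so shot noise shrinks with the attenuated
#' signal). Two electronic components do not scale with the signal:
#' Gaussian read noise (`noise_sigma`) and scan-line offset noise
#' (`line_sigma`, one random offset per scan row, as produced by detector
#' drift in line-scanning microscopes). Line noise is spectrally sparse —
#' it loads a single spatial-frequency column — so once depth attenuation
#' removes the dense shot-noise floor, the spectrum tail is a mostly flat
#' noise bed with a few strong line-noise coefficients. That raises the
#' tail kurtosis of deep, signal-starved slices, which is exactly the
#' degradation signature the quality module is designed to detect.
#'
#' @param height,width Image size in pixels.
#' @param pixel_size_um Micrometres per pixel (default 0.5).
#' @param background_level Neuropil background as a fraction of dynamic
#'   range, in (0, 1).
#' @param cell_density_normal,cell_density_tumor Cell-body densities in
#'   cells per mm^2; tumor must be at least normal (equality gives the
#'   degenerate uniform case used by boundary-ramp edge cases). The defaults (300 vs. 1200)
#'   are appearance-level choices sized so a 256x256 px window at
#'   0.5 um/px contains several cells; they are not claims about biology.
#' @param cell_radius_um Range (min, max) of cell-body radii in um.
#' @param nucleus_contrast Brightness of the dim nucleus inside the dark
#'   cell body, as a fraction of the background level.
#' @param fiber_count Number of bright curvilinear fibers.
#' @param fiber_width_um Fiber cross-section (Gaussian sigma ~ width / 2).
#' @param depth_decay_per_um Exponential structure-contrast loss rate with
#'   imaging depth (>= 0).
#' @param noise_sigma Gaussian detector read-noise scale (fraction of
#'   dynamic range).
#' @param shot_photons Photon budget of the shot-noise model: a pixel at
#'   full scale collects this many photons on average.
#' @param line_sigma Scan-line offset noise scale: one Gaussian offset per
#'   image row (fraction of dynamic range).
#' @param psf_sigma_px Gaussian optical point-spread-function sigma in
#'   pixels applied to the noiseless structure.
#' @param seed Default RNG seed used when an operation is not given one.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(height = 256L, width = 256L, pixel_size_um = 0.5,
                           background_level = 0.35,
                           cell_density_normal = 300,
                           cell_density_tumor = 1200,
                           cell_radius_um = c(4, 8),
                           nucleus_contrast = 0.5,
                           fiber_count = 8L, fiber_width_um = 1.5,
                           depth_decay_per_um = 0.03,
                           noise_sigma = 0.01,
                           shot_photons = 200,
                           line_sigma = 0.003,
                           psf_sigma_px = 0.8,
                           seed = 1L) {
  stopifnot(height >= 16, width >= 16, pixel_size_um > 0,
            background_level > 0, background_level < 1,
            cell_density_normal >= 0,
            cell_density_tumor >= cell_density_normal,
            length(cell_radius_um) == 2, all(cell_radius_um > 0),
            diff(cell_radius_um) >= 0, nucleus_contrast >= 0,
            fiber_count >= 0, fiber_width_um > 0,
            noise_sigma >= 0, shot_photons > 0,
            line_sigma >= 0, psf_sigma_px >= 0)
  if (depth_decay_per_um < 0) {
    stop_thgqc("depth_decay_per_um must be >= 0",
               class = "thgqc_param_error")
  }
  structure(as.list(environment()), class = "phantom_params")
}

phantom_density <- function(params, class_label) {
  switch(match.arg(class_label, c("normal", "tumor")),
         normal = params$cell_density_normal,
         tumor = params$cell_density_tumor)
}

check_coverage <- function(params, density) {
  mean_r_mm <- mean(params$cell_radius_um) / 1000
  coverage <- density * pi * mean_r_mm^2
  if (coverage > 0.5) {
    stop_thgqc(sprintf(
      "cell density %g/mm^2 with radii %g-%g um implies %.0f%% area coverage (> 50%%); phantom unrealistic",
      density, params$cell_radius_um[1], params$cell_radius_um[2],
      100 * coverage), class = "thgqc_param_error")
  }
  invisible(coverage)
}

# Gaussian fiber stamp kernel (odd-sized square), peak 1.
fiber_kernel <- function(sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  d <- seq(-r, r)
  k <- exp(-outer(d^2, d^2, `+`) / (2 * sigma_px^2))
  k
}

stamp_max <- function(canvas, kernel, ci, cj) {
  r <- (nrow(kernel) - 1L) / 2L
  H <- nrow(canvas); W <- ncol(canvas)
  i0 <- max(1L, ci - r); i1 <- min(H, ci + r)
  j0 <- max(1L, cj - r); j1 <- min(W, cj + r)
  if (i0 > i1 || j0 > j1) return(canvas)
  ki <- (i0:i1) - ci + r + 1L
  kj <- (j0:j1) - cj + r + 1L
  canvas[i0:i1, j0:j1] <- pmax(canvas[i0:i1, j0:j1], kernel[ki, kj])
  canvas
}

# Render the noiseless structural signal plus ground-truth masks.
render_structure <- function(params, class_label, density = NULL) {
  H <- params$height; W <- params$width
  px <- params$pixel_size_um
  bg <- params$background_level
  density <- density %||% phantom_density(params, class_label)
  check_coverage(params, density)

  fiber_map <- matrix(0, H, W)
  if (params$fiber_count > 0) {
    sigma_px <- params$fiber_width_um / 2 / px
    kern <- fiber_kernel(sigma_px)
    n_steps <- ceiling(1.5 * (H + W))
    for (f in seq_len(params$fiber_count)) {
      i <- runif(1, 1, H); j <- runif(1, 1, W)
      ang <- runif(1, 0, 2 * pi)
      for (s in seq_len(n_steps)) {
        ang <- ang + rnorm(1, 0, 0.12)
        i <- i + sin(ang); j <- j + cos(ang)
        if (i < -3 * sigma_px || i > H + 3 * sigma_px ||
            j < -3 * sigma_px || j > W + 3 * sigma_px) break
        fiber_map <- stamp_max(fiber_map, kern, round(i), round(j))
      }
    }
  }
  fiber_mask <- fiber_map > exp(-2)

  area_mm2 <- (H * px / 1000) * (W * px / 1000)
  n_cells <- rpois(1, density * area_mm2)
  cell_mask <- matrix(FALSE, H, W)
  body_level <- 0.15 * bg
  nucleus_level <- params$nucleus_contrast * bg
  cell_alpha <- matrix(0, H, W)      # body coverage
  nuc_alpha <- matrix(0, H, W)       # nucleus coverage
  if (n_cells > 0) {
    ci <- runif(n_cells, 1, H); cj <- runif(n_cells, 1, W)
    cr <- runif(n_cells, params$cell_radius_um[1], params$cell_radius_um[2]) / px
    for (c in seq_len(n_cells)) {
      r <- cr[c]
      i0 <- max(1L, floor(ci[c] - r - 1)); i1 <- min(H, ceiling(ci[c] + r + 1))
      j0 <- max(1L, floor(cj[c] - r - 1)); j1 <- min(W, ceiling(cj[c] + r + 1))
      if (i0 > i1 || j0 > j1) next
      dd <- sqrt(outer(((i0:i1) - ci[c])^2, ((j0:j1) - cj[c])^2, `+`))
      a <- pmin(pmax(r - dd + 0.5, 0), 1)          # anti-aliased disc
      an <- pmin(pmax(0.45 * r - dd + 0.5, 0), 1)  # interior nucleus
      cell_alpha[i0:i1, j0:j1] <- pmax(cell_alpha[i0:i1, j0:j1], a)
      nuc_alpha[i0:i1, j0:j1] <- pmax(nuc_alpha[i0:i1, j0:j1], an)
      cell_mask[i0:i1, j0:j1] <- cell_mask[i0:i1, j0:j1] | (a > 0.5)
    }
  }

  fiber_level <- min(1, bg + 0.45)
  s <- bg + fiber_map * (fiber_level - bg)
  s <- s * (1 - cell_alpha) + cell_alpha * body_level
  s <- s * (1 - nuc_alpha) + nuc_alpha * nucleus_level
  if (params$psf_sigma_px > 0) {
    s <- EBImage::gblur(s, sigma = params$psf_sigma_px)
  }
  list(signal = s, cell_mask = cell_mask, fiber_mask = fiber_mask,
       n_cells = n_cells)
}

# Apply depth attenuation and the detector noise model, returning 16-bit
# integer pixels. `contrast` attenuates the whole structural signal
# (THG signal loss with depth); the electronic noise terms (read noise and
# scan-line offsets) do not scale with it.
apply_detector <- function(signal, params, contrast = 1) {
  H <- nrow(signal); W <- ncol(signal)
  s <- contrast * signal
  out <- matrix(rpois(length(s), pmax(s, 0) * params$shot_photons) /
                  params$shot_photons, H, W)
  if (params$noise_sigma > 0) out <- out + rnorm(length(s), 0, params$noise_sigma)
  if (params$line_sigma > 0) out <- out + rnorm(H, 0, params$line_sigma)
  out <- pmin(pmax(out, 0), 1)
  round(out * 65535)
}

#' Render a synthetic THG tissue image
#'
#' Draws Poisson-distributed dark cell bodies (with dim interior nuclei) at
#' the class's density, bright smoothed-random-walk fibers, and the
#' detector noise model of [phantom_params()]. Deterministic given
#' `(params, class_label, seed)`.
#'
#' @param params A [phantom_params()].
#' @param class_label `"normal"` or `"tumor"` (selects the cell density).
#' @param seed RNG seed (defaults to `params$seed`).
#' @param contrast Structure contrast multiplier (1 = surface slice).
#' @param case_id,depth_index Metadata forwarded to the record.
#' @return A list with `image` (16-bit [image_record()]), `cell_mask` and
#'   `fiber_mask` (logical matrices), and `n_cells` (rendered cell count).
#' @export
render_tissue_image <- function(params, class_label = c("normal", "tumor"),
                                seed = params$seed, contrast = 1,
                                case_id = NA_character_, depth_index = NULL) {
  class_label <- match.arg(class_label)
  with_seed(seed, function() {
    st <- render_structure(params, class_label)
    pix <- apply_detector(st$signal, params, contrast)
    rec <- image_record(pix, params$pixel_size_um, 16L, case_id,
                        depth_index = depth_index, label = class_label)
    list(image = rec, cell_mask = st$cell_mask, fiber_mask = st$fiber_mask,
         n_cells = st$n_cells)
  })
}

#' Render a depth-degraded z-stack phantom
#'
#' All slices share one structural layout; slice `k` (0-based) has its
#' structure contrast scaled by `exp(-depth_decay_per_um * k *
#' depth_step_um)` while the detector noise terms are unchanged, so the
#' signal-to-noise ratio decreases monotonically with depth — the phantom
#' analogue of THG signal loss beyond the penetration depth.
#'
#' @param params A [phantom_params()].
#' @param class_label `"normal"` or `"tumor"`.
#' @param n_slices Number of slices (>= 2).
#' @param depth_step_um Slice spacing in micrometres.
#' @param seed RNG seed.
#' @param case_id Case identifier.
#' @return A [zstack()] of 16-bit slices with `depth_index` 0..n-1.
#' @export
render_zstack <- function(params, class_label = c("normal", "tumor"),
                          n_slices = 6L, depth_step_um = 15,
                          seed = params$seed, case_id = NA_character_) {
  class_label <- match.arg(class_label)
  stopifnot(n_slices >= 2, depth_step_um > 0)
  st <- with_seed(derive_seed(seed, "structure"), function()
    render_structure(params, class_label))
  slices <- lapply(seq_len(n_slices) - 1L, function(k) {
    contrast <- exp(-params$depth_decay_per_um * k * depth_step_um)
    pix <- with_seed(derive_seed(seed, "slice", k), function()
      apply_detector(st$signal, params, contrast))
    image_record(pix, params$pixel_size_um, 16L, case_id,
                 depth_index = k, label = class_label)
  })
  zstack(slices, depth_step_um)
}

#' Render a tumor-boundary mosaic phantom
#'
#' Cell density ramps linearly left-to-right from the normal to the tumor
#' density, emulating a mosaic spanning histologically normal tissue, the
#' infiltration boundary and tumor tissue. The reference mask labels
#' columns whose local density is below the midpoint as normal (1) and the
#' rest as tumor (2).
#'
#' @param params A [phantom_params()]; `height`/`width` give the mosaic
#'   size (width should be at least 4x the overlay window size).
#' @param seed RNG seed.
#' @param case_id Case identifier.
#' @return A [thg_mosaic()] with a `reference_mask`.
#' @export
render_boundary_mosaic <- function(params, seed = params$seed,
                                   case_id = NA_character_) {
  H <- params$height; W <- params$width
  px <- params$pixel_size_um
  d0 <- params$cell_density_normal
  d1 <- params$cell_density_tumor
  with_seed(seed, function() {
    check_coverage(params, d1)
    # render structure with cells from an inhomogeneous Poisson process:
    # density(x) = d0 + (d1 - d0) * x / W across columns
    area_mm2 <- (H * px / 1000) * (W * px / 1000)
    mean_density <- (d0 + d1) / 2
    base <- render_structure(params, "normal", density = 1e-9)  # fibers only
    n_cells <- rpois(1, mean_density * area_mm2)
    s <- base$signal
    cell_mask <- matrix(FALSE, H, W)
    bg <- params$background_level
    body_level <- 0.15 * bg
    nucleus_level <- params$nucleus_contrast * bg
    if (n_cells > 0) {
      u <- runif(n_cells)
      # inverse CDF of the linear density ramp in x (column direction)
      xj <- if (d1 > d0) {
        W * (sqrt(d0^2 + u * (d1^2 - d0^2)) - d0) / (d1 - d0)
      } else {
        W * u
      }
      ci <- runif(n_cells, 1, H)
      cr <- runif(n_cells, params$cell_radius_um[1],
                  params$cell_radius_um[2]) / px
      for (c in seq_len(n_cells)) {
        r <- cr[c]
        i0 <- max(1L, floor(ci[c] - r - 1)); i1 <- min(H, ceiling(ci[c] + r + 1))
        j0 <- max(1L, floor(xj[c] - r - 1)); j1 <- min(W, ceiling(xj[c] + r + 1))
        if (i0 > i1 || j0 > j1) next
        dd <- sqrt(outer(((i0:i1) - ci[c])^2, ((j0:j1) - xj[c])^2, `+`))
        a <- pmin(pmax(r - dd + 0.5, 0), 1)
        an <- pmin(pmax(0.45 * r - dd + 0.5, 0), 1)
        blk <- s[i0:i1, j0:j1]
        blk <- blk * (1 - a) + a * body_level
        blk <- blk * (1 - an) + an * nucleus_level
        s[i0:i1, j0:j1] <- blk
        cell_mask[i0:i1, j0:j1] <- cell_mask[i0:i1, j0:j1] | (a > 0.5)
      }
    }
    pix <- apply_detector(s, params, contrast = 1)
    col_density <- d0 + (d1 - d0) * (seq_len(W) - 0.5) / W
    ref_class <- ifelse(col_density < (d0 + d1) / 2, 1L, 2L)
    ref <- matrix(rep(ref_class, each = H), H, W)
    mos <- thg_mosaic(pix, px, case_id, reference_mask = ref)
    mos$cell_mask <- cell_mask
    mos
  })
}

#' Specification of a synthetic multi-case dataset
#'
#' @param n_normal_cases,n_tumor_cases Number of cases per class (>= 1).
#' @param images_per_case Range (min, max) of 2-D images per tumor case.
#' @param normal_fraction Target fraction of normal images in the dataset
#'   (default 0.097, a heavily imbalanced training set).
#' @param stack_fraction Fraction of images acquired as 3-slice z-stacks
#'   rather than single shots.
#' @param depth_step_um Slice spacing of generated stacks.
#' @param seed Master RNG seed.
#' @return An object of class `dataset_spec`.
#' @export
dataset_spec <- function(n_normal_cases = 4L, n_tumor_cases = 15L,
                         images_per_case = c(4L, 8L),
                         normal_fraction = 0.097, stack_fraction = 0.25,
                         depth_step_um = 5, seed = 1L) {
  if (n_normal_cases < 1 || n_tumor_cases < 1) {
    stop_thgqc("need at least one case per class",
               class = "thgqc_param_error")
  }
  stopifnot(length(images_per_case) == 2, images_per_case[1] >= 1,
            images_per_case[2] >= images_per_case[1],
            normal_fraction > 0, normal_fraction < 1,
            stack_fraction >= 0, stack_fraction <= 1)
  structure(as.list(environment()), class = "dataset_spec")
}

#' Generate a synthetic multi-case dataset on disk
#'
#' Writes 16-bit TIFF phantoms (single images and multi-page z-stacks) and
#' a `manifest.csv` binding images to cases and case-level diagnoses.
#' Tumor cases draw their image counts from `images_per_case`; normal-case
#' image counts are then sized so the image-level class imbalance is near
#' `normal_fraction`. All labels are inherited from the case diagnosis
#' (weak labels). Deterministic given the spec seed: a rerun produces a
#' byte-identical manifest.
#'
#' @param spec A [dataset_spec()].
#' @param params A [phantom_params()] shared by all images.
#' @param out_dir Output directory (must not already contain a manifest
#'   unless `overwrite = TRUE`).
#' @param overwrite Overwrite an existing dataset.
#' @return The `case_manifest` (invisibly also written to
#'   `out_dir/manifest.csv`).
#' @export
generate_dataset <- function(spec, params, out_dir, overwrite = FALSE) {
  stopifnot(inherits(spec, "dataset_spec"), inherits(params, "phantom_params"))
  manifest_path <- file.path(out_dir, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite) {
    stop_thgqc("dataset already exists at ", out_dir,
               " (use overwrite = TRUE)", class = "thgqc_exists_error")
  }
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  plan <- with_seed(spec$seed, function() {
    n_tum <- sample(spec$images_per_case[1]:spec$images_per_case[2],
                    spec$n_tumor_cases, replace = TRUE)
    total_tumor <- sum(n_tum)
    total_normal <- max(spec$n_normal_cases,
                        round(total_tumor * spec$normal_fraction /
                                (1 - spec$normal_fraction)))
    n_norm <- rep(total_normal %/% spec$n_normal_cases, spec$n_normal_cases)
    extra <- total_normal - sum(n_norm)
    if (extra > 0) n_norm[seq_len(extra)] <- n_norm[seq_len(extra)] + 1L
    n_norm <- pmax(n_norm, 1L)
    list(n_tum = n_tum, n_norm = n_norm)
  })
  rows <- list()
  emit_case <- function(case_id, diagnosis, n_images) {
    label <- if (diagnosis == "glioma") "tumor" else "normal"
    remaining <- n_images
    item <- 0L
    while (remaining > 0) {
      item <- item + 1L
      seed_i <- derive_seed(spec$seed, case_id, item)
      make_stack <- with_seed(derive_seed(seed_i, "plan"), function()
        remaining >= 3 && runif(1) < spec$stack_fraction)
      if (make_stack) {
        zs <- render_zstack(params, label, n_slices = 3L,
                            depth_step_um = spec$depth_step_um,
                            seed = seed_i, case_id = case_id)
        fn <- sprintf("%s_stack%02d.tif", case_id, item)
        write_thg_image(zs, file.path(out_dir, "images", fn))
        for (k in seq_along(zs$slices)) {
          rows[[length(rows) + 1L]] <<- data.frame(
            image_path = file.path("images", fn), case_id = case_id,
            diagnosis = diagnosis, split_role = "train",
            pixel_size_um = params$pixel_size_um, depth_index = k - 1L)
        }
        remaining <- remaining - length(zs$slices)
      } else {
        r <- render_tissue_image(params, label, seed = seed_i,
                                 case_id = case_id)
        fn <- sprintf("%s_img%02d.tif", case_id, item)
        write_thg_image(r$image, file.path(out_dir, "images", fn))
        rows[[length(rows) + 1L]] <<- data.frame(
          image_path = file.path("images", fn), case_id = case_id,
          diagnosis = diagnosis, split_role = "train",
          pixel_size_um = params$pixel_size_um, depth_index = NA_integer_)
        remaining <- remaining - 1L
      }
    }
  }
  for (i in seq_len(spec$n_normal_cases)) {
    emit_case(sprintf("norm%02d", i), "epilepsy", plan$n_norm[i])
  }
  for (i in seq_len(spec$n_tumor_cases)) {
    emit_case(sprintf("tum%02d", i), "glioma", plan$n_tum[i])
  }
  manifest <- validate_manifest(do.call(rbind, rows))
  write_manifest(manifest, manifest_path)
  invisible(manifest)
}
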