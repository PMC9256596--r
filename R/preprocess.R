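#' Preprocessing configuration
#'
#' Ingestion standardizes every image to a common physical pixel size (so
#' tissue structures occupy a fixed number of pixels regardless of the
#' acquisition scan mode) and then pseudo min-max normalizes intensities to
#' the 8-bit range using robust quantiles, which fixes the data range while
#' absorbing hot-pixel outliers.
#'
#' @param target_pixel_size_um Target pixel size (default 0.5 um).
#' @param low_quantile,high_quantile Robust normalization quantiles
#'   (defaults 0.01 and 0.99, i.e. the 1st and 99th percentiles).
#' @param min_dim Minimum allowed output side length in pixels; resampling
#'   below this fails (the classifier cannot accept smaller inputs).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_pixel_size_um = 0.5,
                              low_quantile = 0.01, high_quantile = 0.99,
                              min_dim = 16L) {
  stopifnot(target_pixel_size_um > 0, low_quantile >= 0,
            low_quantile < high_quantile, high_quantile <= 1, min_dim >= 1)
  structure(list(target_pixel_size_um = target_pixel_size_um,
                 low_quantile = low_quantile,
                 high_quantile = high_quantile,
                 min_dim = as.integer(min_dim)),
            class = "preprocess_config")
}

#' Resample an image to the target physical pixel size
#'
#' Output dimensions are `round(dim * pixel_size_um / target)`. Bilinear
#' interpolation is used in both directions; when downscaling by more than
#' 1.5x a Gaussian anti-aliasing blur is applied first. An image already at
#' the target size is returned unchanged (no resampling).
#'
#' @param image An [image_record()].
#' @param config A [preprocess_config()].
#' @return An [image_record()] at the target pixel size.
#' @export
standardize_pixel_size <- function(image, config = preprocess_config()) {
  stopifnot(inherits(image, "image_record"))
  target <- config$target_pixel_size_um
  if (isTRUE(all.equal(image$pixel_size_um, target))) return(image)
  factor <- image$pixel_size_um / target
  new_dim <- round(dim(image$pixels) * factor)
  if (min(new_dim) < config$min_dim) {
    stop_thgqc("resampled size ", new_dim[1], "x", new_dim[2],
               " below the ", config$min_dim, " px minimum",
               class = "thgqc_size_error")
  }
  m <- image$pixels
  if (factor < 1 / 1.5) {
    # anti-alias before strong downscaling: sigma ~ half the scale ratio
    m <- EBImage::gblur(m, sigma = 0.5 / factor)
  }
  m <- EBImage::resize(m, w = new_dim[1], h = new_dim[2],
                       filter = "bilinear")
  maxval <- 2^image$bit_depth - 1
  m <- matrix(pmin(pmax(round(m), 0), maxval), new_dim[1], new_dim[2])
  image_record(m, target, image$bit_depth, image$case_id,
               depth_index = image$depth_index, label = image$label)
}

#' Pseudo min-max normalize to 8-bit range
#'
#' Computes the `low_quantile` and `high_quantile` intensity quantiles
#' (linear interpolation between order statistics), linearly rescales so
#' those map to 0 and 255, clips, and rounds to 8-bit integers. A constant
#' image (equal quantiles) maps to all zeros with a warning.
#'
#' @param image An [image_record()].
#' @param config A [preprocess_config()].
#' @return An 8-bit [image_record()].
#' @export
pseudo_minmax_to_8bit <- function(image, config = preprocess_config()) {
  stopifnot(inherits(image, "image_record"))
  x <- image$pixels
  q <- quantile(x, c(config$low_quantile, config$high_quantile),
                names = FALSE, type = 7)
  if (q[2] <= q[1]) {
    warning("degenerate normalization (q_low == q_high); output all zeros")
    out <- matrix(0L, nrow(x), ncol(x))
  } else {
    scaled <- pmin(pmax((x - q[1]) / (q[2] - q[1]), 0), 1)
    out <- matrix(as.integer(floor(scaled * 255 + 0.5)), nrow(x), ncol(x))
  }
  image_record(out, image$pixel_size_um, 8L, image$case_id,
               depth_index = image$depth_index, label = image$label)
}

#' Preprocess one image: pixel-size standardization then normalization
#'
#' @param image An [image_record()].
#' @param config A [preprocess_config()].
#' @return An 8-bit [image_record()] at the target pixel size.
#' @export
preprocess_image <- function(image, config = preprocess_config()) {
  pseudo_minmax_to_8bit(standardize_pixel_size(image, config), config)
}
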