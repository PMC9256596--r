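#' High-frequency tail of an image's power spectrum
#'
#' Computes the 2-D discrete Fourier transform of the mean-subtracted
#' image, takes squared magnitudes, assigns each coefficient a normalized
#' radial frequency r in \[0, sqrt(2)\] (1 = Nyquist along the shorter
#' axis), and returns the multiset of power values with `r >= 1 -
#' freq_frac`, excluding the DC term. Noise in the image domain raises the
#' variety and extremity of these high-frequency coefficients, which the
#' downstream tail statistics quantify.
#'
#' The tail is the radial (isotropic) generalization of a 1-D spectrum
#' tail and is invariant to 90-degree rotations; an azimuthally averaged
#' 1-D profile is available via [radial_power_profile()] for
#' cross-checking.
#'
#' @param image An [image_record()] or a numeric matrix (at least 16x16).
#' @param freq_frac Fraction of the radial Nyquist range treated as high
#'   frequencies (e.g. 0.2 for the top 20%).
#' @param log_power Return log1p of the power values instead of raw power.
#' @return An object of class `spectrum_tail` with elements `freq_frac`
#'   and `power_values`.
#' @export
power_spectrum_tail <- function(image, freq_frac, log_power = FALSE) {
  m <- if (inherits(image, "image_record")) image$pixels else image
  stopifnot(is.matrix(m))
  if (nrow(m) < 16 || ncol(m) < 16) {
    stop_thgqc("image must be at least 16x16 for spectral statistics",
               class = "thgqc_value_error")
  }
  if (anyNA(m) || any(!is.finite(m))) {
    stop_thgqc("non-finite pixels in spectral input",
               class = "thgqc_value_error")
  }
  stopifnot(freq_frac > 0, freq_frac <= 1)
  r <- radial_frequency_grid(dim(m))
  keep <- r >= 1 - freq_frac & r > 0   # r > 0 drops the DC term
  if (!any(keep)) {
    stop_thgqc("freq_frac ", freq_frac, " selects an empty tail",
               class = "thgqc_value_error")
  }
  pw <- Mod(fft(m - mean(m)))^2
  vals <- pw[keep]
  if (log_power) vals <- log1p(vals)
  structure(list(freq_frac = freq_frac, power_values = vals,
                 n_coefficients = sum(keep)),
            class = "spectrum_tail")
}

# Normalized radial frequency of every DFT coefficient of an h x w image:
# per-axis signed frequencies in cycles/pixel, radius divided by the 0.5
# cycles/pixel Nyquist of the shorter axis.
radial_frequency_grid <- function(dims) {
  fr <- function(n) {
    k <- 0:(n - 1)
    ifelse(k <= n %/% 2, k, k - n) / n
  }
  fy <- fr(dims[1])
  fx <- fr(dims[2])
  sqrt(outer(fy^2, fx^2, `+`)) / 0.5
}

#' Azimuthally averaged 1-D power profile
#'
#' Averages the 2-D power spectrum over rings of normalized radial
#' frequency, for cross-checking the radial tail definition.
#'
#' @param image An [image_record()] or matrix.
#' @param n_bins Number of radial bins spanning r in (0, 1\].
#' @return A data frame with `r` (bin centers) and `power` (ring means).
#' @export
radial_power_profile <- function(image, n_bins = 64L) {
  m <- if (inherits(image, "image_record")) image$pixels else image
  r <- radial_frequency_grid(dim(m))
  pw <- Mod(fft(m - mean(m)))^2
  sel <- r > 0 & r <= 1
  bins <- pmin(ceiling(r[sel] * n_bins), n_bins)
  data.frame(r = (seq_len(n_bins) - 0.5) / n_bins,
             power = as.numeric(tapply(pw[sel], factor(bins, seq_len(n_bins)),
                                       mean)))
}

#' Descriptive statistics of a spectrum tail
#'
#' Returns the seven statistics used for frequency-domain quality ranking:
#' mean, inverse mean, standard deviation, inverse standard deviation,
#' coefficient of variation, kurtosis and skewness. Moments are population
#' moments; kurtosis is the Pearson (non-excess) fourth standardized
#' moment `m4 / m2^2` (3 for a Gaussian) and skewness is `m3 / m2^1.5`.
#' A zero-variance tail yields `NaN` kurtosis and skewness sentinels.
#'
#' @param tail A `spectrum_tail` (or bare numeric vector of power values).
#' @return An object of class `tail_stats`.
#' @export
tail_statistics <- function(tail) {
  x <- if (inherits(tail, "spectrum_tail")) tail$power_values else tail
  if (length(x) == 0) {
    stop_thgqc("empty spectrum tail", class = "thgqc_value_error")
  }
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  stdev <- sqrt(m2)
  structure(list(
    mean = mu,
    inverse_mean = if (mu > 0) 1 / mu else NaN,
    std = stdev,
    inverse_std = if (stdev > 0) 1 / stdev else NaN,
    coefficient_of_variation = if (mu > 0) stdev / mu else NaN,
    kurtosis = if (m2 > 0) m4 / m2^2 else NaN,
    skewness = if (m2 > 0) m3 / m2^1.5 else NaN,
    n = length(x)), class = "tail_stats")
}

#' @export
print.tail_stats <- function(x, ...) {
  cat(sprintf(paste0("<tail_stats n=%d mean=%.4g sd=%.4g cv=%.4g ",
                     "kurtosis=%.4g skewness=%.4g>\n"),
              x$n, x$mean, x$std, x$coefficient_of_variation,
              x$kurtosis, x$skewness))
  invisible(x)
}

#' Tail kurtosis of an image
#'
#' Convenience wrapper: Pearson kurtosis of the top `freq_frac` power
#' spectrum tail.
#'
#' @inheritParams power_spectrum_tail
#' @return Scalar kurtosis (NaN for a degenerate spectrum).
#' @export
tail_kurtosis <- function(image, freq_frac = 0.2, log_power = FALSE) {
  tail_statistics(power_spectrum_tail(image, freq_frac, log_power))$kurtosis
}

#' A training-set exclusion rule
#'
#' A quality condition pairs a tail fraction with a kurtosis cutoff:
#' images whose tail kurtosis exceeds the cutoff are excluded from the
#' training set. Condition (`NA`, `NA`) is the identity rule that excludes
#' nothing. Exactly one field set is a configuration error.
#'
#' @param freq_frac Tail fraction in (0, 1\], or `NA` for no filtering.
#' @param kurtosis_cutoff Positive cutoff, or `NA` for no filtering.
#' @return An object of class `quality_condition`.
#' @export
quality_condition <- function(freq_frac = NA, kurtosis_cutoff = NA) {
  if (is.na(freq_frac) != is.na(kurtosis_cutoff)) {
    stop_thgqc("freq_frac and kurtosis_cutoff must both be set or both NA",
               class = "thgqc_config_error")
  }
  if (!is.na(freq_frac)) {
    stopifnot(freq_frac > 0, freq_frac <= 1, kurtosis_cutoff > 0)
  }
  structure(list(freq_frac = freq_frac, kurtosis_cutoff = kurtosis_cutoff),
            class = "quality_condition")
}

#' @export
format.quality_condition <- function(x, ...) {
  if (is.na(x$freq_frac)) "None-None"
  else sprintf("%g%%-%g", 100 * x$freq_frac, x$kurtosis_cutoff)
}

#' @export
print.quality_condition <- function(x, ...) {
  cat("<quality_condition ", format(x), ">\n", sep = "")
  invisible(x)
}

#' The seven canonical training-data conditions
#'
#' The default sweep: no filtering, then tail fractions 40%, 20% and 10%
#' crossed with kurtosis cutoffs 10 and 5.
#'
#' @return List of [quality_condition()]s.
#' @export
default_conditions <- function() {
  list(quality_condition(NA, NA),
       quality_condition(0.4, 10), quality_condition(0.4, 5),
       quality_condition(0.2, 10), quality_condition(0.2, 5),
       quality_condition(0.1, 10), quality_condition(0.1, 5))
}

#' Apply a quality condition to a set of images
#'
#' An image is excluded iff its tail kurtosis (at the condition's
#' frequency fraction) strictly exceeds the kurtosis cutoff. The
#' (`NA`, `NA`) condition excludes nothing. This filter is intended for
#' training data only: a held-out test set is never quality-filtered.
#'
#' @param images List of [image_record()]s or matrices (common pixel
#'   size assumed).
#' @param condition A [quality_condition()].
#' @param ids Image identifiers (defaults to names or indices).
#' @param exclude_degenerate Treat NaN kurtosis (zero-variance tail, e.g.
#'   a constant image) as excluded.
#' @return A `quality_report` data frame with per-image `id`, `kurtosis`
#'   and `excluded`, plus attributes `condition`, `n_images`,
#'   `n_excluded`, `fraction_excluded`.
#' @export
apply_quality_condition <- function(images, condition,
                                    ids = NULL,
                                    exclude_degenerate = TRUE) {
  stopifnot(inherits(condition, "quality_condition"))
  if (length(images) == 0) {
    stop_thgqc("empty image set", class = "thgqc_value_error")
  }
  ids <- ids %||% names(images) %||% as.character(seq_along(images))
  if (is.na(condition$freq_frac)) {
    kurt <- rep(NA_real_, length(images))
    excl <- rep(FALSE, length(images))
  } else {
    kurt <- vapply(images, tail_kurtosis, numeric(1),
                   freq_frac = condition$freq_frac)
    excl <- ifelse(is.nan(kurt), exclude_degenerate,
                   kurt > condition$kurtosis_cutoff)
  }
  rep <- data.frame(id = ids, kurtosis = kurt, excluded = excl,
                    stringsAsFactors = FALSE)
  attr(rep, "condition") <- condition
  attr(rep, "n_images") <- length(images)
  attr(rep, "n_excluded") <- sum(excl)
  attr(rep, "fraction_excluded") <- mean(excl)
  class(rep) <- c("quality_report", "data.frame")
  rep
}

#' Per-slice tail kurtosis across a z-stack
#'
#' One kurtosis per slice in depth order; optionally normalized by a
#' reference maximum (for visualization across a subset of stacks).
#'
#' @param zstack A [zstack()] with at least 2 slices.
#' @param freq_frac Tail fraction.
#' @param normalize_to Positive reference value to divide by, or `NULL`.
#' @return Numeric vector of per-slice kurtosis values.
#' @export
stack_kurtosis_profile <- function(zstack, freq_frac = 0.2,
                                   normalize_to = NULL) {
  stopifnot(inherits(zstack, "zstack"))
  if (length(zstack$slices) < 2) {
    stop_thgqc("stack needs at least 2 slices", class = "thgqc_value_error")
  }
  prof <- vapply(zstack$slices, function(s)
    tail_kurtosis(s, freq_frac), numeric(1))
  if (!is.null(normalize_to)) {
    if (normalize_to <= 0) {
      stop_thgqc("normalize_to must be positive", class = "thgqc_value_error")
    }
    prof <- prof / normalize_to
  }
  prof
}

#' Sweep a set of quality conditions over an image set
#'
#' Tabulates, for each condition, how many images its exclusion rule would
#' remove from a training set.
#'
#' @param images List of [image_record()]s or matrices.
#' @param conditions List of [quality_condition()]s (default: the seven
#'   canonical conditions).
#' @param ... Passed to [apply_quality_condition()].
#' @return A data frame with one row per condition (`condition`,
#'   `freq_frac`, `kurtosis_cutoff`, `n_excluded`, `fraction_excluded`);
#'   the per-condition reports are attached as attribute `reports`.
#' @export
condition_sweep <- function(images, conditions = default_conditions(), ...) {
  if (length(images) == 0) {
    stop_thgqc("empty image set", class = "thgqc_value_error")
  }
  reports <- lapply(conditions, function(cond)
    apply_quality_condition(images, cond, ...))
  out <- data.frame(
    condition = vapply(conditions, format, character(1)),
    freq_frac = vapply(conditions, function(c) c$freq_frac, numeric(1)),
    kurtosis_cutoff = vapply(conditions, function(c) c$kurtosis_cutoff,
                             numeric(1)),
    n_excluded = vapply(reports, attr, numeric(1), which = "n_excluded"),
    fraction_excluded = vapply(reports, attr, numeric(1),
                               which = "fraction_excluded"))
  attr(out, "reports") <- reports
  out
}
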