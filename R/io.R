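#' Construct an image record
#'
#' The elementary container of the package: a single-channel intensity image
#' with its physical pixel size, bit depth, case linkage and (weak) label.
#'
#' @param pixels Non-negative integer-valued matrix within the declared bit
#'   depth.
#' @param pixel_size_um Micrometres per pixel (> 0).
#' @param bit_depth 16 (raw acquisition) or 8 (preprocessed).
#' @param case_id Opaque case identifier string.
#' @param depth_index Optional non-negative slice position within a z-stack.
#' @param label One of `"normal"`, `"tumor"`, `"unlabeled"`.
#' @return An object of class `image_record`.
#' @export
image_record <- function(pixels, pixel_size_um, bit_depth = 16L,
                         case_id = NA_character_, depth_index = NULL,
                         label = "unlabeled") {
  stopifnot(is.matrix(pixels), length(pixels) > 0)
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop_thgqc("image contains non-finite pixels", class = "thgqc_value_error")
  }
  if (!bit_depth %in% c(8L, 16L)) {
    stop_thgqc("bit_depth must be 8 or 16", class = "thgqc_value_error")
  }
  if (min(pixels) < 0 || max(pixels) > 2^bit_depth - 1) {
    stop_thgqc("pixel values outside the declared ", bit_depth,
               "-bit range", class = "thgqc_value_error")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      is.na(pixel_size_um) || pixel_size_um <= 0) {
    stop_thgqc("pixel_size_um must be a positive number",
               class = "thgqc_metadata_error")
  }
  label <- match.arg(label, c("normal", "tumor", "unlabeled"))
  if (!is.null(depth_index)) stopifnot(depth_index >= 0)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 bit_depth = as.integer(bit_depth),
                 case_id = as.character(case_id),
                 depth_index = depth_index, label = label),
            class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record %dx%d px, %d-bit, %.3g um/px, case %s, %s%s>\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$pixel_size_um,
              x$case_id, x$label,
              if (!is.null(x$depth_index))
                sprintf(", depth %d", x$depth_index) else ""))
  invisible(x)
}

#' Construct a z-stack of image records
#'
#' @param slices List of [image_record()]s sharing case id, pixel size and
#'   shape, with strictly increasing `depth_index`.
#' @param depth_step_um Physical spacing between slices in micrometres.
#' @return An object of class `zstack`.
#' @export
zstack <- function(slices, depth_step_um = 1) {
  stopifnot(length(slices) >= 1, depth_step_um > 0)
  dims <- vapply(slices, function(s) dim(s$pixels), integer(2))
  if (length(unique(dims[1, ])) > 1 || length(unique(dims[2, ])) > 1) {
    stop_thgqc("all z-stack slices must share one shape",
               class = "thgqc_value_error")
  }
  di <- vapply(slices, function(s) s$depth_index %||% NA_integer_, numeric(1))
  if (anyNA(di) || any(diff(di) <= 0)) {
    stop_thgqc("slice depth_index must be strictly increasing",
               class = "thgqc_value_error")
  }
  structure(list(slices = slices, depth_step_um = depth_step_um),
            class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  cat(sprintf("<zstack of %d slices, %dx%d px, step %.3g um>\n",
              length(x$slices), nrow(x$slices[[1]]$pixels),
              ncol(x$slices[[1]]$pixels), x$depth_step_um))
  invisible(x)
}

#' Construct a mosaic (large stitched field of view)
#'
#' @param pixels Intensity matrix.
#' @param pixel_size_um Micrometres per pixel.
#' @param case_id Case identifier.
#' @param reference_mask Optional integer class-label matrix of the same
#'   shape, with codes 0 = background, 1 = normal, 2 = tumor.
#' @param bit_depth Bit depth of `pixels`.
#' @return An object of class `thg_mosaic`.
#' @export
thg_mosaic <- function(pixels, pixel_size_um, case_id = NA_character_,
                       reference_mask = NULL, bit_depth = 16L) {
  rec <- image_record(pixels, pixel_size_um, bit_depth, case_id)
  if (!is.null(reference_mask)) {
    if (!identical(dim(reference_mask), dim(pixels))) {
      stop_thgqc("reference_mask shape differs from mosaic",
                 class = "thgqc_value_error")
    }
    stopifnot(all(reference_mask %in% 0:2))
  }
  structure(c(rec, list(reference_mask = reference_mask)),
            class = c("thg_mosaic", "image_record"))
}

## ---- TIFF I/O ----

#' Read a THG image or z-stack from TIFF
#'
#' Reads a single- or multi-page grayscale TIFF bit-exactly. Multi-page
#' files become a [zstack()] with `depth_index` equal to page order. The
#' physical pixel size comes from the manifest (or the `pixel_size_um`
#' argument); TIFF resolution tags are honored when present, but an
#' explicitly supplied value wins on conflict, since acquisition-software
#' metadata is unreliable across devices.
#'
#' @param path Path to the TIFF file.
#' @param pixel_size_um Pixel size in micrometres; required when the file
#'   carries no resolution tag.
#' @param case_id,label,depth_step_um Metadata forwarded to the record.
#' @return An [image_record()] (single page) or [zstack()] (multi-page).
#' @export
read_thg_image <- function(path, pixel_size_um = NULL,
                           case_id = NA_character_, label = "unlabeled",
                           depth_step_um = 1) {
  if (!file.exists(path)) {
    stop_thgqc("file not found: ", path, class = "thgqc_not_found_error")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  info <- attributes(pages[[1]])
  first <- pages[[1]]
  if (length(dim(first)) == 3 && dim(first)[3] > 1) {
    stop_thgqc("multi-channel TIFF not supported (grayscale only): ", path,
               class = "thgqc_format_error")
  }
  if (is.double(pages[[1]]) && any(pages[[1]] != round(pages[[1]]))) {
    stop_thgqc("floating-point TIFF not supported: ", path,
               class = "thgqc_format_error")
  }
  bits <- info$bits.per.sample %||% NA
  if (!isTRUE(bits %in% c(8, 16))) {
    stop_thgqc("only 8- and 16-bit grayscale TIFF supported: ", path,
               class = "thgqc_format_error")
  }
  if (is.null(pixel_size_um)) pixel_size_um <- tiff_pixel_size(info)
  if (is.null(pixel_size_um)) {
    stop_thgqc("pixel size missing for ", path,
               ": supply it via the manifest or pixel_size_um",
               class = "thgqc_metadata_error")
  }
  recs <- lapply(seq_along(pages), function(i) {
    m <- pages[[i]]
    if (length(dim(m)) == 3) m <- m[, , 1]
    attributes(m) <- list(dim = dim(m))   # drop TIFF tag attributes
    image_record(m, pixel_size_um, bit_depth = as.integer(bits),
                 case_id = case_id,
                 depth_index = if (length(pages) > 1) i - 1L else NULL,
                 label = label)
  })
  if (length(recs) == 1) recs[[1]] else zstack(recs, depth_step_um)
}

tiff_pixel_size <- function(info) {
  xres <- info$x.resolution %||% NULL
  if (is.null(xres) || !is.finite(xres) || xres <= 0) return(NULL)
  unit <- info$resolution.unit %||% "inch"
  per_um <- switch(as.character(unit),
                   inch = xres / 25400, cm = xres / 10000, NULL)
  if (is.null(per_um)) return(NULL)
  1 / per_um
}

#' Write an image record (or plain matrix) to TIFF
#'
#' @param x An [image_record()], [zstack()] or integer matrix.
#' @param path Output path.
#' @param bit_depth Bit depth used when `x` is a plain matrix.
#' @return `path`, invisibly.
#' @export
write_thg_image <- function(x, path, bit_depth = 16L) {
  if (inherits(x, "zstack")) {
    mats <- lapply(x$slices, function(s) s$pixels / (2^s$bit_depth - 1))
    bits <- x$slices[[1]]$bit_depth
    tiff::writeTIFF(mats, path, bits.per.sample = bits)
    return(invisible(path))
  }
  if (inherits(x, "image_record")) {
    bit_depth <- x$bit_depth
    x <- x$pixels
  }
  tiff::writeTIFF(x / (2^bit_depth - 1), path,
                  bits.per.sample = as.integer(bit_depth))
  invisible(path)
}

## ---- case manifest ----

#' Read and validate a case manifest
#'
#' The manifest is a CSV with header columns `image_path, case_id,
#' diagnosis, split_role` and optional `label`, `pixel_size_um` and
#' `depth_index` columns. Diagnoses are `epilepsy` (histologically normal)
#' or `glioma` (tumor); every image inherits its case's diagnosis as a weak
#' label unless an explicit image-level `label` column overrides it (as for
#' a pathologist-annotated test set). Rows may appear in any order.
#'
#' @param path Path to the manifest CSV.
#' @return A `case_manifest` data frame with a derived `label` column.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop_thgqc("manifest not found: ", path, class = "thgqc_not_found_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(df)
}

#' Validate a manifest data frame
#'
#' @param df Data frame with manifest columns (see [read_manifest()]).
#' @return The validated `case_manifest`.
#' @export
validate_manifest <- function(df) {
  required <- c("image_path", "case_id", "diagnosis", "split_role")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_thgqc("manifest missing columns: ", paste(missing, collapse = ", "),
               class = "thgqc_validation_error")
  }
  # a multi-page stack file appears once per slice, distinguished by
  # depth_index; otherwise each 2-D image is exactly one row
  key <- paste(df$image_path,
               if ("depth_index" %in% names(df)) df$depth_index else "")
  dup <- df$image_path[duplicated(key)]
  if (length(dup)) {
    stop_thgqc("duplicate image entries: ", paste(unique(dup), collapse = ", "),
               class = "thgqc_validation_error")
  }
  cases_per_image <- tapply(df$case_id, df$image_path,
                            function(x) length(unique(x)))
  if (any(cases_per_image > 1)) {
    stop_thgqc("image assigned to more than one case: ",
               paste(names(cases_per_image)[cases_per_image > 1],
                     collapse = ", "),
               class = "thgqc_validation_error")
  }
  bad <- !df$diagnosis %in% c("epilepsy", "glioma")
  if (any(bad)) {
    stop_thgqc("unknown diagnosis in rows ",
               paste(which(bad), collapse = ", "),
               " (expected epilepsy or glioma)",
               class = "thgqc_validation_error")
  }
  bad_role <- !df$split_role %in% c("train", "test")
  if (any(bad_role)) {
    stop_thgqc("split_role must be train or test (rows ",
               paste(which(bad_role), collapse = ", "), ")",
               class = "thgqc_validation_error")
  }
  weak <- ifelse(df$diagnosis == "glioma", "tumor", "normal")
  if ("label" %in% names(df)) {
    explicit <- !is.na(df$label) & nzchar(df$label)
    if (any(explicit & !df$label %in% c("normal", "tumor"))) {
      stop_thgqc("image-level labels must be normal or tumor",
                 class = "thgqc_validation_error")
    }
    df$label <- ifelse(explicit, df$label, weak)
  } else {
    df$label <- weak
  }
  class(df) <- c("case_manifest", "data.frame")
  df
}

#' Write a case manifest to CSV
#'
#' @param manifest A `case_manifest` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- overlay output ----

#' Write a score map and class mask as TIFF overlays
#'
#' Writes the sliding-window score map as an 8-bit TIFF (scores in \[0,1\]
#' scaled to 0..255, rounding halves up) and the class mask as an 8-bit
#' TIFF of integer class codes (0 background, 1 normal, 2 tumor). The mask
#' round-trips losslessly through [read_thg_image()].
#'
#' @param path_prefix Output path prefix; `<prefix>_scores.tif` and
#'   `<prefix>_mask.tif` are written.
#' @param score_map Numeric matrix of scores in \[0,1\] (NA allowed only
#'   where `mask` is background).
#' @param mask Integer class-code matrix (same shape).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_overlay <- function(path_prefix, score_map, mask) {
  stopifnot(is.matrix(score_map), is.matrix(mask),
            identical(dim(score_map), dim(mask)))
  scores <- score_map
  scores[is.na(scores) & mask == 0] <- 0
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop_thgqc("score map contains NaN over covered pixels",
               class = "thgqc_value_error")
  }
  if (min(scores) < 0 || max(scores) > 1) {
    stop_thgqc("score map values must lie in [0,1]",
               class = "thgqc_value_error")
  }
  score_path <- paste0(path_prefix, "_scores.tif")
  mask_path <- paste0(path_prefix, "_mask.tif")
  write_thg_image(floor(scores * 255 + 0.5), score_path, bit_depth = 8L)
  write_thg_image(mask, mask_path, bit_depth = 8L)
  invisible(c(scores = score_path, mask = mask_path))
}
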