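# Image + sidecar I/O. Images are plain single-channel 8-bit PNG or TIFF;
# physical metadata travels in a JSON sidecar with the same basename, so the
# image file stays a standard raster that any viewer opens.

#' Construct an image record
#'
#' The container consumed by every downstream module: an 8-bit grayscale pixel
#' grid plus the physical pixel spacing and scan-plane metadata. Pixel
#' coordinates are 1-based `(row, col)` with pixel centers at integer
#' coordinates; the physical position of pixel `(r, c)` is
#' `((r-1)*spacing_row, (c-1)*spacing_col)` millimetres.
#'
#' @param pixels integer matrix with values in 0..255 (rows = image rows).
#' @param spacing_mm numeric length-2, millimetres per pixel as `(row, col)`;
#'   both strictly positive and finite.
#' @param view `"transverse"` or `"longitudinal"`.
#' @param subject_id subject identifier string.
#' @param sex `"F"`, `"M"` or `NA`.
#' @param group_label reference label: `"pos"`, `"neg"` or `"unknown"`.
#' @return An object of class `qus_image`.
#' @export
image_record <- function(pixels, spacing_mm, view, subject_id = "unknown",
                         sex = NA_character_, group_label = "unknown") {
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    qus_stop("`pixels` must be a non-empty matrix", "qus_format_error")
  }
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L) {
    qus_stop("pixel values must be integers in [0, 255]", "qus_format_error")
  }
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 2L ||
      !all(is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    qus_stop("`spacing_mm` must be two finite positive numbers (row, col)",
             "qus_metadata_error")
  }
  if (!is.na(sex)) {
    if (!sex %in% c("F", "M")) {
      qus_stop("`sex` must be \"F\", \"M\" or NA", "qus_metadata_error")
    }
  }
  structure(
    list(
      pixels = pixels,
      spacing_mm = as.numeric(spacing_mm),
      view = match_view(view),
      subject_id = as.character(subject_id),
      sex = sex,
      group_label = match_label(group_label)
    ),
    class = "qus_image"
  )
}

#' @export
print.qus_image <- function(x, ...) {
  cat(sprintf(
    "<qus_image> %s view, %d x %d px @ (%.4g, %.4g) mm/px, subject %s [%s]\n",
    x$view, nrow(x$pixels), ncol(x$pixels),
    x$spacing_mm[1], x$spacing_mm[2], x$subject_id, x$group_label
  ))
  invisible(x)
}

sidecar_path_for <- function(image_path) {
  paste0(sub("\\.[A-Za-z]+$", "", image_path), ".json")
}

read_sidecar <- function(sidecar_path) {
  if (!file.exists(sidecar_path)) {
    qus_stop(sprintf("sidecar not found: %s", sidecar_path), "qus_metadata_error")
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(meta$spacing_mm)) {
    qus_stop(sprintf("sidecar %s lacks \"spacing_mm\"", sidecar_path),
             "qus_metadata_error")
  }
  if (is.null(meta$view)) {
    qus_stop(sprintf("sidecar %s lacks \"view\"", sidecar_path),
             "qus_metadata_error")
  }
  meta
}

read_pixels <- function(image_path) {
  ext <- tolower(sub(".*\\.", "", image_path))
  if (ext == "png") {
    raw <- png::readPNG(image_path)
    if (length(dim(raw)) == 3L) {
      qus_stop("multi-channel PNG: expected single-channel 8-bit grayscale",
               "qus_format_error")
    }
    scaled <- raw * 255
    if (max(abs(scaled - round(scaled))) > 1e-6) {
      qus_stop("PNG is not 8-bit grayscale (intensities not multiples of 1/255)",
               "qus_format_error")
    }
    round(scaled)
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(image_path, as.is = TRUE)
    if (length(dim(raw)) == 3L) {
      qus_stop("multi-channel TIFF: expected single-channel 8-bit grayscale",
               "qus_format_error")
    }
    if (max(raw) > 255 || min(raw) < 0) {
      qus_stop("TIFF exceeds 8-bit range [0, 255]", "qus_format_error")
    }
    raw
  } else {
    qus_stop(sprintf("unsupported image extension: .%s", ext), "qus_format_error")
  }
}

#' Read an image and its JSON metadata sidecar
#'
#' @param image_path path to a single-channel 8-bit PNG or TIFF.
#' @param sidecar_path path to the JSON sidecar; defaults to the image path
#'   with its extension replaced by `.json`. The sidecar must carry
#'   `spacing_mm` (row, col mm/pixel) and `view`, and may carry `subject_id`,
#'   `sex`, `group_label` and a stored `roi` specification.
#' @return A [image_record()] with, when present in the sidecar, the ROI
#'   specification attached as attribute `"roi"`.
#' @export
read_image <- function(image_path, sidecar_path = NULL) {
  if (!file.exists(image_path)) {
    qus_stop(sprintf("image not found: %s", image_path), "qus_format_error")
  }
  sidecar_path <- sidecar_path %||% sidecar_path_for(image_path)
  meta <- read_sidecar(sidecar_path)
  px <- read_pixels(image_path)
  img <- image_record(
    pixels = px,
    spacing_mm = as.numeric(meta$spacing_mm),
    view = meta$view,
    subject_id = meta$subject_id %||% sub("\\.[A-Za-z]+$", "", basename(image_path)),
    sex = if (is.null(meta$sex)) NA_character_ else meta$sex,
    group_label = meta$group_label %||% "unknown"
  )
  if (!is.null(meta$roi)) {
    attr(img, "roi") <- roi_spec(
      shape = meta$roi$shape,
      center = as.numeric(meta$roi$center_px),
      area_mm2 = meta$roi$area_mm2 %||% 2
    )
  }
  img
}

#' Write an image and its JSON metadata sidecar
#'
#' @param image a [image_record()].
#' @param image_path output path ending in `.png`, `.tif` or `.tiff`.
#' @param roi optional [roi_spec()] stored in the sidecar so later
#'   quantification reuses the calibrated region.
#' @return `image_path`, invisibly.
#' @export
write_image <- function(image, image_path, roi = NULL) {
  stopifnot(inherits(image, "qus_image"))
  ext <- tolower(sub(".*\\.", "", image_path))
  norm <- image$pixels / 255
  if (ext == "png") {
    png::writePNG(norm, image_path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, image_path, bits.per.sample = 8L)
  } else {
    qus_stop(sprintf("unsupported image extension: .%s", ext), "qus_format_error")
  }
  meta <- list(
    spacing_mm = image$spacing_mm,
    view = image$view,
    subject_id = image$subject_id,
    sex = if (is.na(image$sex)) NULL else image$sex,
    group_label = image$group_label
  )
  if (!is.null(roi)) {
    meta$roi <- list(shape = roi$shape, center_px = roi$center,
                     area_mm2 = roi$area_mm2)
  }
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       sidecar_path_for(image_path),
                       auto_unbox = TRUE, digits = 10)
  invisible(image_path)
}
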