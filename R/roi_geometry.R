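# ROI rasterization: a physical-area specification (circle for the transverse
# view, square for the longitudinal view) becomes an explicit pixel mask under
# the image's mm-per-pixel spacing. Pixel-center inclusion, closed boundary.

#' Specify a region of interest by physical area
#'
#' The protocol fixes the ROI's physical area (default 2 mm^2) rather than its
#' pixel count; a circle is used on the transverse view and a square on the
#' longitudinal view.
#'
#' @param shape `"circle"` or `"square"`.
#' @param center ROI center as `(row, col)` in 1-based pixel coordinates; may
#'   be fractional.
#' @param area_mm2 target physical area in mm^2 (> 0), default 2.
#' @return An object of class `qus_roi_spec`.
#' @export
roi_spec <- function(shape = c("circle", "square"), center, area_mm2 = 2) {
  shape <- match.arg(shape)
  if (!is.numeric(center) || length(center) != 2L || !all(is.finite(center))) {
    qus_stop("`center` must be two finite numbers (row, col)", "qus_usage_error")
  }
  if (!is_scalar_number(area_mm2) || area_mm2 <= 0) {
    qus_stop("`area_mm2` must be a positive number", "qus_usage_error")
  }
  structure(list(shape = shape, center = as.numeric(center),
                 area_mm2 = area_mm2),
            class = "qus_roi_spec")
}

# Block start index whose centroid is nearest `center`; ties toward smaller
# indices. `d` is the ideal (possibly fractional) start.
block_start <- function(center, side_px) {
  ceiling(center - (side_px - 1) / 2 - 0.5)
}

#' Rasterize an ROI specification into a pixel mask
#'
#' Circle: pixel `(r, c)` is included iff the Euclidean distance from its
#' center to the ROI center, measured in millimetres under the per-axis
#' spacing, is `<=` the radius `sqrt(area_mm2 / pi)` (closed disk). Square:
#' an axis-aligned block of `round(sqrt(area_mm2) / spacing)` pixels per axis
#' (minimum 1, computed per axis under anisotropic spacing), placed so its
#' centroid is nearest the requested center, ties toward smaller indices.
#' An ROI that extends beyond the image raises a geometry error; there is no
#' silent clipping. Mismatched shape/view conventions (circle on a
#' longitudinal image, square on a transverse one) warn but proceed.
#'
#' @param spec a [roi_spec()].
#' @param image a [image_record()].
#' @return An object of class `qus_mask`: `coords` (n x 2 integer matrix of
#'   1-based row, col), `n_pixels`, `achieved_area_mm2`
#'   (= `n_pixels * spacing_row * spacing_col`), `spacing_mm`.
#' @export
roi_pixel_mask <- function(spec, image) {
  stopifnot(inherits(spec, "qus_roi_spec"), inherits(image, "qus_image"))
  expected <- c(circle = "transverse", square = "longitudinal")[[spec$shape]]
  if (image$view != expected) {
    warning(sprintf("%s ROI is conventionally used on the %s view (image is %s)",
                    spec$shape, expected, image$view), call. = FALSE)
  }
  sp <- image$spacing_mm
  nr <- nrow(image$pixels)
  nc <- ncol(image$pixels)
  ctr <- spec$center
  if (ctr[1] < 1 || ctr[1] > nr || ctr[2] < 1 || ctr[2] > nc) {
    qus_stop("ROI center lies outside the image", "qus_geometry_error")
  }
  if (spec$shape == "circle") {
    r_mm <- sqrt(spec$area_mm2 / pi)
    # pixel (1,1) owns [0.5, 1.5] in pixel units; the disk must fit inside
    # the physical image extent
    if (ctr[1] - r_mm / sp[1] < 0.5 || ctr[1] + r_mm / sp[1] > nr + 0.5 ||
        ctr[2] - r_mm / sp[2] < 0.5 || ctr[2] + r_mm / sp[2] > nc + 0.5) {
      qus_stop("circular ROI extends beyond the image bounds", "qus_geometry_error")
    }
    r0 <- max(1L, floor(ctr[1] - r_mm / sp[1]))
    r1 <- min(nr, ceiling(ctr[1] + r_mm / sp[1]))
    c0 <- max(1L, floor(ctr[2] - r_mm / sp[2]))
    c1 <- min(nc, ceiling(ctr[2] + r_mm / sp[2]))
    rr <- r0:r1
    cc <- c0:c1
    d2 <- outer((rr - ctr[1]) * sp[1], rep(1, length(cc)))^2 +
      outer(rep(1, length(rr)), (cc - ctr[2]) * sp[2])^2
    inside <- which(d2 <= r_mm^2, arr.ind = TRUE)
    coords <- cbind(row = rr[inside[, 1]], col = cc[inside[, 2]])
  } else {
    side_mm <- sqrt(spec$area_mm2)
    side_r <- max(1L, as.integer(floor(side_mm / sp[1] + 0.5)))
    side_c <- max(1L, as.integer(floor(side_mm / sp[2] + 0.5)))
    r0 <- block_start(ctr[1], side_r)
    c0 <- block_start(ctr[2], side_c)
    if (r0 < 1 || r0 + side_r - 1 > nr || c0 < 1 || c0 + side_c - 1 > nc) {
      qus_stop("square ROI extends beyond the image bounds", "qus_geometry_error")
    }
    coords <- as.matrix(expand.grid(row = r0:(r0 + side_r - 1),
                                    col = c0:(c0 + side_c - 1)))
  }
  storage.mode(coords) <- "integer"
  structure(
    list(coords = coords,
         n_pixels = nrow(coords),
         achieved_area_mm2 = nrow(coords) * sp[1] * sp[2],
         spacing_mm = sp),
    class = "qus_mask"
  )
}

#' Advisory checks on a rasterized ROI
#'
#' The protocol calls for more than 2000 pixels and a 2 mm^2 area; at coarse
#' native spacings those two constraints can conflict, so both are advisory.
#'
#' @param mask a [roi_pixel_mask()] result.
#' @param target_area_mm2 intended physical area (default 2).
#' @param min_pixels pixel-count floor (default 2000).
#' @param area_tol relative tolerance on the achieved area (default 0.05).
#' @return Character vector of warnings (empty when all checks pass).
#' @export
validate_roi <- function(mask, target_area_mm2 = 2, min_pixels = 2000,
                         area_tol = 0.05) {
  stopifnot(inherits(mask, "qus_mask"))
  warnings <- character()
  if (mask$n_pixels <= min_pixels) {
    warnings <- c(warnings, sprintf(
      "ROI has %d pixels; the protocol calls for more than %d",
      mask$n_pixels, min_pixels))
  }
  rel <- abs(mask$achieved_area_mm2 - target_area_mm2) / target_area_mm2
  if (rel > area_tol) {
    warnings <- c(warnings, sprintf(
      "achieved area %.4f mm^2 deviates %.1f%% from the %.4g mm^2 target",
      mask$achieved_area_mm2, 100 * rel, target_area_mm2))
  }
  warnings
}
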