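#' Lesion image: 2D intensity array plus binary region-of-interest mask
#'
#' The unit of radiomic extraction: a single 2D grayscale slice on a
#' Hounsfield-unit-like intensity scale, a binary mask delineating the
#' lesion, and the physical pixel size.  The mask must be a single
#' connected component (8-connectivity) and, for texture features to be
#' meaningful, should cover at least 25 pixels.
#'
#' @param intensity numeric matrix of intensities (HU-like scale).
#' @param mask binary (0/1 or logical) matrix, same dimensions as
#'   `intensity`; 1 marks lesion pixels.
#' @param pixel_size_cm physical edge length of one pixel, in cm.
#' @return an object of class `lesion_image` with elements `intensity`,
#'   `mask` (logical matrix) and `pixel_size_cm`.
#' @export
lesion_image <- function(intensity, mask, pixel_size_cm) {
  intensity <- as.matrix(intensity)
  mask <- as.matrix(mask)
  if (!all(dim(intensity) == dim(mask)))
    stop("intensity and mask must have identical dimensions")
  if (!all(mask %in% c(0, 1, TRUE, FALSE)))
    stop("mask must be binary (0/1)")
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (!any(mask)) stop("mask is empty")
  if (!is.numeric(pixel_size_cm) || length(pixel_size_cm) != 1L ||
      pixel_size_cm <= 0)
    stop("pixel_size_cm must be a single positive number")
  if (any(!is.finite(intensity[mask])))
    stop("non-finite intensities inside the mask")
  structure(
    list(intensity = intensity, mask = mask,
         pixel_size_cm = pixel_size_cm),
    class = "lesion_image"
  )
}

#' @export
print.lesion_image <- function(x, ...) {
  cat(sprintf(
    "<lesion_image> %d x %d px, %.3f cm/px, ROI %d px (%.2f cm^2)\n",
    nrow(x$intensity), ncol(x$intensity), x$pixel_size_cm,
    sum(x$mask), sum(x$mask) * x$pixel_size_cm^2))
  invisible(x)
}

#' Number of 8-connected components of a binary mask
#' @keywords internal
#' @noRd
n_components <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  max(lab)
}

assert_connected <- function(mask) {
  if (n_components(mask) != 1L)
    stop("mask must be a single connected component")
  invisible(TRUE)
}

#' Quantize in-mask intensities to G gray levels
#'
#' Equal-width binning of in-mask intensities between the in-mask minimum
#' and maximum.  A constant ROI maps entirely to level 1.  Quantization is
#' monotone in intensity, so all downstream matrix features are invariant
#' to affine intensity shifts.
#'
#' @param img a [lesion_image()].
#' @param levels number of gray levels G (>= 2).
#' @return an object of class `quantized_roi`: `levels`, and `quantized`, a
#'   matrix of labels in 1..G inside the mask and `NA` outside.
#' @export
quantize <- function(img, levels = 64L) {
  stopifnot(inherits(img, "lesion_image"))
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2")
  v <- img$intensity[img$mask]
  lo <- min(v); hi <- max(v)
  q <- matrix(NA_integer_, nrow(img$intensity), ncol(img$intensity))
  if (hi == lo) {
    q[img$mask] <- 1L
  } else {
    lab <- floor((img$intensity[img$mask] - lo) / (hi - lo) * levels) + 1L
    q[img$mask] <- pmin.int(as.integer(lab), levels)
  }
  structure(list(levels = levels, quantized = q), class = "quantized_roi")
}

#' Write / read a lesion image as 16-bit grayscale TIFF pairs
#'
#' Intensities are stored at 1/16 HU resolution with a fixed offset of
#' 1024 HU (representable range -1024 to +3071.94 HU); masks are stored as
#' 0/1.  Values generated by [generate_lesion()] are pre-rounded to 1/16 HU
#' so the round trip is exact.
#'
#' @param img a [lesion_image()].
#' @param image_path,mask_path TIFF file paths.
#' @export
write_lesion_tiff <- function(img, image_path, mask_path) {
  stopifnot(inherits(img, "lesion_image"))
  enc <- round((img$intensity + 1024) * 16)
  if (any(enc < 0 | enc > 65535))
    stop("intensity out of encodable range [-1024, 3071.94] HU")
  tiff::writeTIFF(enc / 65535, image_path, bits.per.sample = 16L)
  tiff::writeTIFF((img$mask * 1) / 65535, mask_path, bits.per.sample = 16L)
  invisible(c(image = image_path, mask = mask_path))
}

#' @rdname write_lesion_tiff
#' @param pixel_size_cm pixel size to attach on read.
#' @export
read_lesion_tiff <- function(image_path, mask_path, pixel_size_cm) {
  enc <- round(tiff::readTIFF(image_path) * 65535)
  m <- round(tiff::readTIFF(mask_path) * 65535)
  lesion_image(enc / 16 - 1024, m != 0, pixel_size_cm)
}
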