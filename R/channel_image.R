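#' Photon-counting channel image
#'
#' A single 2D grayscale image of nonnegative integer photon counts, as
#' produced by avalanche-photodiode detection on a STED/confocal microscope,
#' together with the metadata every downstream computation needs: the channel
#' label, the imaging modality and the pixel size (default 30 nm, the
#' acquisition convention all area computations assume).
#'
#' @param pixels Integer matrix of nonnegative counts (rows x cols).
#' @param channel Channel label, e.g. `"nf"`, `"marker"`, `"volume"`.
#' @param modality `"STED"` or `"confocal"`.
#' @param pixel_size_nm Pixel size in nanometres (> 0).
#' @param image_id Identifier shared by all channels of one field of view.
#' @param round_id Experimental round (imaging session) identifier.
#'
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel = "unknown",
                          modality = c("STED", "confocal"),
                          pixel_size_nm = 30, image_id = "img",
                          round_id = NA_character_) {
  modality <- match.arg(modality)
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (is.double(pixels)) {
    if (any(pixels != round(pixels), na.rm = TRUE))
      stop("`pixels` must hold integer photon counts; got non-integer values")
    storage.mode(pixels) <- "integer"
  }
  if (!is.integer(pixels)) stop("`pixels` must be an integer matrix")
  if (anyNA(pixels)) stop("`pixels` contains NA")
  if (any(pixels < 0L)) stop("photon counts must be nonnegative")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 ||
      pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be a single positive number")
  structure(
    list(pixels = pixels, channel = channel, modality = modality,
         pixel_size_nm = pixel_size_nm, image_id = image_id,
         round_id = round_id),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf(
    "<channel_image> %s [%s] %dx%d px @ %g nm/px (image %s, round %s)\n",
    x$channel, x$modality, nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm,
    x$image_id, x$round_id))
  cat(sprintf("  counts: min %d, max %d, mean %.2f\n",
              min(x$pixels), max(x$pixels), mean(x$pixels)))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

as_channel_pixels <- function(img) {
  if (inherits(img, "channel_image")) img$pixels else img
}

with_pixels <- function(img, pixels) {
  if (inherits(img, "channel_image")) {
    img$pixels <- pixels
    img
  } else {
    pixels
  }
}

#' Offset the minimum image intensity to zero
#'
#' Subtracts the global minimum count from every pixel, so the dimmest pixel
#' becomes 0. Applied before non-zero-pixel statistics so that "non-zero"
#' means "above the detector floor". Pixel ordering is preserved and the
#' operation is idempotent on images whose minimum is already 0.
#'
#' @param img A [channel_image()] or integer matrix.
#' @return Same type as the input, with `min(pixels) == 0`.
#' @export
offset_min_to_zero <- function(img) {
  px <- as_channel_pixels(img)
  with_pixels(img, px - min(px))
}

#' Binary analysis mask
#'
#' A logical pixel mask with a provenance string recording how it was built
#' (e.g. `"counts>=4"`, `"saturate(1e-04)|otsu>3"`, `"roi&counts>=4"`).
#'
#' @param pixels Logical matrix.
#' @param source Provenance string.
#' @return An object of class `pixel_mask`.
#' @export
pixel_mask <- function(pixels, source = "manual") {
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("mask `pixels` must be a logical matrix")
  if (anyNA(pixels)) stop("mask contains NA")
  structure(list(pixels = pixels, source = source), class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf("<pixel_mask> %dx%d, %d px set, source: %s\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels), x$source))
  invisible(x)
}

as_mask_pixels <- function(m) {
  if (inherits(m, "pixel_mask")) m$pixels else m
}

check_same_shape <- function(a, b, what = "inputs") {
  da <- dim(as_matrix_any(a)); db <- dim(as_matrix_any(b))
  if (!identical(da, db))
    stop(sprintf("%s must share the same shape (%s vs %s)", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  invisible(TRUE)
}

as_matrix_any <- function(x) {
  if (inherits(x, "channel_image")) x$pixels
  else if (inherits(x, "pixel_mask")) x$pixels
  else x
}
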