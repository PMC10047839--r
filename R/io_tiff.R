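#' Read a photon-count channel from a single-plane grayscale TIFF
#'
#' Counts are kept as integers end-to-end: the 4-count background threshold
#' used for neurofilament STED channels is only well defined on raw counts,
#' so floating-point or RGB TIFFs are rejected rather than coerced.
#'
#' @param path TIFF file (8- or 16-bit unsigned, single plane, grayscale).
#' @inheritParams channel_image
#' @return A [channel_image()].
#' @export
read_channel_tiff <- function(path, channel = "unknown",
                              modality = c("STED", "confocal"),
                              pixel_size_nm = 30, image_id = NULL,
                              round_id = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) != 2)
    stop("unsupported format: ", path,
         " is not a single-plane grayscale image (dims ",
         paste(dim(px), collapse = "x"), ")")
  if (is.double(px) && (any(px != round(px)) || any(px < 0)))
    stop("unsupported format: ", path,
         " holds floating-point samples; photon-count TIFFs required")
  if (any(px < 0))
    stop("unsupported format: ", path, " holds negative samples ",
         "(not an unsigned-integer photon-count TIFF)")
  if (is.null(image_id))
    image_id <- sub("\\.tiff?$", "", basename(path), ignore.case = TRUE)
  channel_image(px, channel = channel, modality = match.arg(modality),
                pixel_size_nm = pixel_size_nm, image_id = image_id,
                round_id = round_id)
}

#' Write a channel image as an uncompressed 16-bit grayscale TIFF
#'
#' @param img A [channel_image()] or integer matrix of counts in [0, 65535].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_channel_tiff <- function(img, path) {
  px <- as_channel_pixels(img)
  if (max(px) > 65535L)
    stop("counts exceed 16-bit range; cannot write ", path)
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}
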