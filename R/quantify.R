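#' Quantify signal inside one ROI analysis mask
#'
#' The per-ROI metrics: pixel count, area in square micrometres
#' (`n_pixels * (pixel_size_nm/1000)^2`), mean count over masked pixels, and
#' the amount metric — ROI area times ROI mean intensity, which equals the
#' pixel area times the summed masked counts. An empty mask yields all-zero
#' metrics by convention (a spine with no signal above threshold).
#'
#' @param img A [channel_image()] (or matrix plus `pixel_size_nm`).
#' @param analysis_mask A [pixel_mask()] or logical matrix, same shape.
#' @param roi_id Identifier copied into the output.
#' @param pixel_size_nm Pixel size; taken from `img` when it is a
#'   [channel_image()].
#' @param round_id,excluded Bookkeeping columns copied into the output.
#' @return One-row [tibble::tibble()] with columns `roi_id`, `n_pixels`,
#'   `area_um2`, `mean_intensity`, `amount`, `round_id`, `excluded`.
#' @export
quantify_roi <- function(img, analysis_mask, roi_id = "roi",
                         pixel_size_nm = NULL, round_id = NA_character_,
                         excluded = FALSE) {
  px <- as_channel_pixels(img)
  m <- as_mask_pixels(analysis_mask)
  check_same_shape(px, m, "image and mask")
  if (is.null(pixel_size_nm))
    pixel_size_nm <- if (inherits(img, "channel_image")) img$pixel_size_nm
                     else 30
  quantify_idx(px, which(m), pixel_size_nm, roi_id = roi_id,
               round_id = round_id, excluded = excluded)
}

quantify_idx <- function(px, idx, pixel_size_nm, roi_id = "roi",
                         round_id = NA_character_, excluded = FALSE) {
  n <- length(idx)
  px_area_um2 <- (pixel_size_nm / 1000)^2
  mean_int <- if (n == 0) 0 else sum(px[idx]) / n
  area <- n * px_area_um2
  tibble::tibble(roi_id = as.character(roi_id), n_pixels = n,
                 area_um2 = area, mean_intensity = mean_int,
                 amount = area * mean_int, round_id = round_id,
                 excluded = excluded)
}

#' Mean intensity over non-zero masked pixels
#'
#' The compartment intensity measure: total masked counts divided by the
#' number of non-zero masked pixels. Images should be offset so their
#' minimum is 0 first (see [offset_min_to_zero()]).
#'
#' @param img A [channel_image()] or integer matrix.
#' @param mask Non-empty [pixel_mask()] or logical matrix.
#' @return Mean count over masked pixels with count > 0; `0` (with a
#'   warning) when every masked pixel is zero.
#' @export
mean_intensity_nonzero <- function(img, mask) {
  px <- as_channel_pixels(img)
  m <- as_mask_pixels(mask)
  check_same_shape(px, m, "image and mask")
  if (!any(m)) stop("empty mask")
  v <- px[m]
  v <- v[v > 0]
  if (length(v) == 0) {
    warning("all masked pixels are zero; returning 0")
    return(0)
  }
  mean(v)
}

#' Axon-to-spine mean intensity ratio
#'
#' Ratio of the mean axonal non-zero-pixel intensity to the mean spine
#' non-zero-pixel intensity, the compartment-enrichment summary for one
#' channel/isoform.
#'
#' @param axon_means,spine_means Numeric vectors of per-ROI
#'   [mean_intensity_nonzero()] values (non-empty).
#' @return A single ratio.
#' @export
axon_spine_ratio <- function(axon_means, spine_means) {
  if (length(axon_means) == 0 || length(spine_means) == 0)
    stop("both compartments must be non-empty")
  denom <- mean(spine_means)
  if (denom == 0) stop("zero spine mean intensity; ratio undefined")
  mean(axon_means) / denom
}

#' Empirical cumulative distribution of per-spine signal area
#'
#' @param quants Tibble of per-spine quantifications (as from
#'   [quantify_roi()]); excluded spines are dropped first.
#' @return A right-continuous step function (class `ecdf`) over `area_um2`.
#' @export
area_ecdf <- function(quants) {
  areas <- quants$area_um2[!quants$excluded]
  if (length(areas) == 0) stop("no spines left after exclusion")
  stats::ecdf(areas)
}

#' Fraction of spines whose signal area exceeds a threshold
#'
#' The occupancy summary: fraction of (non-excluded) spines containing more
#' than `threshold_um2` of signal area, with the per-spine binomial standard
#' error `sqrt(p(1-p)/n)`. When an `image_id` column is present, per-image
#' fractions and their SEM are reported as well (the error-bar convention
#' for image-level replication). The comparison is strict (`>`); at the
#' 30 nm pixel size an exact tie with 0.1 um^2 cannot occur since 0.1 is not
#' a multiple of the 9e-4 um^2 pixel area.
#'
#' @param quants Tibble of per-spine quantifications.
#' @param threshold_um2 Area threshold in square micrometres.
#' @return List with `fraction`, `se`, `n`, and (when available)
#'   `per_image` (tibble) and `sem_images`.
#' @export
fraction_above_area <- function(quants, threshold_um2 = 0.1) {
  q <- quants[!quants$excluded, , drop = FALSE]
  n <- nrow(q)
  if (n == 0) stop("no spines left after exclusion")
  p <- mean(q$area_um2 > threshold_um2)
  out <- list(fraction = p, se = sqrt(p * (1 - p) / n), n = n)
  if ("image_id" %in% names(q)) {
    per <- stats::aggregate(q$area_um2 > threshold_um2,
                            by = list(image_id = q$image_id), FUN = mean)
    names(per)[2] <- "fraction"
    out$per_image <- tibble::as_tibble(per)
    out$sem_images <- if (nrow(per) > 1)
      stats::sd(per$fraction) / sqrt(nrow(per)) else NA_real_
  }
  out
}
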