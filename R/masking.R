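#' Saturate very bright spots
#'
#' Clips the brightest tail of the count histogram to the empirical
#' `1 - tail_fraction` quantile (default 0.01 percent), so isolated very
#' bright spots — aggregates, dust — do not dominate downstream thresholds.
#' At most `ceiling(tail_fraction * n_pixels)` pixels are altered and the
#' transform is monotone non-increasing, so pixel ordering is preserved
#' below the clip level.
#'
#' @param img A [channel_image()] or integer matrix.
#' @param tail_fraction Fraction of the histogram tail to clip, in (0, 1).
#' @return Same type as input, clipped. The clip level is an observed count
#'   (type-1 quantile), so counts stay integers.
#' @export
saturate_bright_spots <- function(img, tail_fraction = 1e-4) {
  if (!is.numeric(tail_fraction) || tail_fraction <= 0 || tail_fraction >= 1)
    stop("`tail_fraction` must be in (0, 1)")
  px <- as_channel_pixels(img)
  q <- as.integer(stats::quantile(px, 1 - tail_fraction, type = 1,
                                  names = FALSE))
  px[px > q] <- q
  with_pixels(img, px)
}

#' Otsu threshold on the integer count histogram
#'
#' Returns the count value `t` maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` of the split into pixels `<= t` and `> t`,
#' searched exhaustively over the integer histogram (no 8-bit rescaling).
#' The associated mask rule is `pixels > t`. Ties are broken toward the
#' smallest threshold.
#'
#' @param img A [channel_image()] or integer matrix with >= 2 distinct values.
#' @return Integer threshold.
#' @export
otsu_threshold <- function(img) {
  px <- as_channel_pixels(img)
  lo <- min(px); hi <- max(px)
  if (lo == hi) stop("degenerate input: constant image has no Otsu threshold")
  counts <- tabulate(as.vector(px) - lo + 1L, nbins = hi - lo + 1L)
  vals <- lo:hi
  n <- sum(counts)
  w0 <- cumsum(counts) / n                 # weight of class {<= t}
  s0 <- cumsum(counts * vals)              # running sum of class {<= t}
  total <- s0[length(s0)]
  # candidates t = lo .. hi-1 (both classes non-empty somewhere in range)
  k <- seq_len(length(vals) - 1L)
  mu0 <- s0[k] / pmax(w0[k] * n, 1)
  w1 <- 1 - w0[k]
  mu1 <- (total - s0[k]) / pmax(w1 * n, 1)
  bcv <- w0[k] * w1 * (mu0 - mu1)^2
  bcv[w0[k] == 0 | w1 == 0] <- -Inf
  as.integer(vals[which.max(bcv)])
}

#' Fixed-count background threshold mask
#'
#' The background mask rule for neurofilament STED channels: a pixel is
#' signal when its photon count reaches `min_counts` (inclusive; default 4).
#'
#' @param img A [channel_image()] or integer matrix.
#' @param min_counts Minimum count for a signal pixel (>= 0).
#' @return A [pixel_mask()].
#' @export
count_threshold_mask <- function(img, min_counts = 4L) {
  if (min_counts < 0) stop("`min_counts` must be >= 0")
  px <- as_channel_pixels(img)
  pixel_mask(px >= min_counts, source = sprintf("counts>=%d", min_counts))
}

#' Rasterize a polygon ROI to a pixel mask
#'
#' A pixel belongs to the mask iff its centre lies inside the polygon under
#' the even-odd rule. Pixel centres sit at integer `(row, col)` coordinates,
#' 0-based; a sliver polygon covering no pixel centre yields a legal empty
#' mask (flagged in the provenance string).
#'
#' @param polygon n x 2 numeric matrix of `(row, col)` vertices (simple
#'   polygon, fully inside the image extent).
#' @param shape Image shape `c(rows, cols)`.
#' @return A [pixel_mask()].
#' @export
rasterize_roi <- function(polygon, shape) {
  idx <- rasterize_polygon_idx(polygon, shape)
  m <- matrix(FALSE, shape[1], shape[2])
  m[idx] <- TRUE
  pixel_mask(m, source = if (length(idx) == 0) "roi(empty)" else "roi")
}

# Linear (1-based, column-major) pixel indices inside a polygon, computed on
# the bounding box only; the workhorse behind rasterize_roi and the
# per-spine loops of the pipeline.
rasterize_polygon_idx <- function(polygon, shape) {
  polygon <- validate_polygon(polygon)
  nr <- shape[1]; nc <- shape[2]
  if (any(polygon[, 1] < -0.5 | polygon[, 1] > nr - 0.5 |
          polygon[, 2] < -0.5 | polygon[, 2] > nc - 0.5))
    stop("polygon extends outside the image extent")
  r0 <- max(0L, floor(min(polygon[, 1]))); r1 <- min(nr - 1L, ceiling(max(polygon[, 1])))
  c0 <- max(0L, floor(min(polygon[, 2]))); c1 <- min(nc - 1L, ceiling(max(polygon[, 2])))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  pr <- rep(rows, times = length(cols))
  pc <- rep(cols, each = length(rows))
  inside <- points_in_polygon(pr, pc, polygon)
  (pr[inside] + 1L) + nr * pc[inside]
}

# Even-odd (ray casting) point-in-polygon test, vectorized over points.
points_in_polygon <- function(pr, pc, poly) {
  inside <- rep(FALSE, length(pr))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    if (yi != yj) {
      cross <- ((yi > pr) != (yj > pr)) &
        (pc < (xj - xi) * (pr - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
    }
    j <- i
  }
  inside
}

#' Second mask: bright-spot saturation followed by thresholding
#'
#' The channel-appropriate signal mask applied on top of the manual spine
#' segmentation: Otsu for synaptic-marker STED channels, the 4-count
#' background threshold for neurofilament STED channels. Bright spots are
#' saturated first in both cases.
#'
#' @param img A [channel_image()] or integer matrix.
#' @param kind `"otsu"` (synaptic marker) or `"counts"` (neurofilament).
#' @param min_counts Count threshold when `kind = "counts"`.
#' @param tail_fraction Passed to [saturate_bright_spots()].
#' @return A [pixel_mask()] whose provenance records both steps.
#' @export
second_mask <- function(img, kind = c("otsu", "counts"), min_counts = 4L,
                        tail_fraction = 1e-4) {
  kind <- match.arg(kind)
  sat <- saturate_bright_spots(img, tail_fraction)
  px <- as_channel_pixels(sat)
  if (kind == "otsu") {
    t <- otsu_threshold(px)
    pixel_mask(px > t,
               source = sprintf("saturate(%g)|otsu>%d", tail_fraction, t))
  } else {
    pixel_mask(px >= min_counts,
               source = sprintf("saturate(%g)|counts>=%d", tail_fraction,
                                min_counts))
  }
}

#' Intersection of a spine ROI mask with its second mask
#'
#' @param spine_mask,second [pixel_mask()]s of the same shape.
#' @return A [pixel_mask()] — the logical AND.
#' @export
spine_analysis_mask <- function(spine_mask, second) {
  check_same_shape(spine_mask, second, "masks")
  pixel_mask(as_mask_pixels(spine_mask) & as_mask_pixels(second),
             source = paste(mask_source(spine_mask), mask_source(second),
                            sep = " & "))
}

mask_source <- function(m) if (inherits(m, "pixel_mask")) m$source else "mask"

#' Flag spines crossed by bright axonal neurofilament signal
#'
#' Spines lying on top of a bright axonal filament cannot be attributed a
#' postsynaptic neurofilament amount and are excluded. A spine is flagged
#' when at least `overlap_fraction` of its pixels fall on the axonal bright
#' mask: axon pixels whose neurofilament count exceeds the `bright_quantile`
#' of the whole NF channel.
#'
#' @param spine_rois A [roi_set()] (its spine-labelled ROIs are used) or a
#'   list of spine polygons.
#' @param nf_img Neurofilament [channel_image()] or matrix.
#' @param axon Axon region: a [pixel_mask()], logical matrix, or [roi_set()]
#'   whose axon-labelled ROIs are rasterized and unioned.
#' @param overlap_fraction Minimum fraction of spine pixels on the axonal
#'   bright mask for the spine to be flagged.
#' @param bright_quantile Quantile of the NF channel defining "bright".
#' @return Named logical vector, one flag per spine ROI.
#' @export
flag_crossed_spines <- function(spine_rois, nf_img, axon,
                                overlap_fraction = 0.1,
                                bright_quantile = 0.95) {
  px <- as_channel_pixels(nf_img)
  shape <- dim(px)
  axon_mask <- if (inherits(axon, "roi_set")) {
    m <- matrix(FALSE, shape[1], shape[2])
    for (r in axon$rois)
      if (r$label == "axon")
        m <- m | as_mask_pixels(rasterize_roi(r$polygon, shape))
    m
  } else as_mask_pixels(axon)
  check_same_shape(px, axon_mask, "image and axon mask")
  bright <- px > stats::quantile(px, bright_quantile, type = 1, names = FALSE)
  axonal_bright <- axon_mask & bright
  spines <- if (inherits(spine_rois, "roi_set"))
    Filter(function(r) r$label == "spine", spine_rois$rois)
  else lapply(seq_along(spine_rois),
              function(i) list(id = as.character(i), polygon = spine_rois[[i]]))
  flags <- vapply(spines, function(r) {
    m <- as_mask_pixels(rasterize_roi(r$polygon, shape))
    n <- sum(m)
    n > 0 && sum(axonal_bright[m]) / n >= overlap_fraction
  }, logical(1))
  names(flags) <- vapply(spines, `[[`, character(1), "id")
  flags
}

#' Cell-level mask from a confocal image
#'
#' Segments the labelled cell from background for whole-field analyses:
#' clip at `saturate_level` of the maximum intensity, median-filter with an
#' 8 x 8 square window to remove noisy pixels, then apply a global Otsu
#' threshold. Returns the foreground mask.
#'
#' @param confocal_img A [channel_image()] or integer matrix (non-constant).
#' @param saturate_level Clip level as a fraction of the maximum intensity.
#' @param median_size Median filter window edge length in pixels.
#' @return A [pixel_mask()].
#' @export
cell_level_mask <- function(confocal_img, saturate_level = 0.9,
                            median_size = 8L) {
  px <- as_channel_pixels(confocal_img)
  if (min(px) == max(px))
    stop("degenerate input: constant image cannot be segmented")
  clip <- as.integer(floor(saturate_level * max(px)))
  px[px > clip] <- clip
  med <- median_filter_square(px, median_size)
  t <- otsu_threshold(med)
  pixel_mask(med > t,
             source = sprintf("saturate(%g*max)|median%dx%d|otsu>%d",
                              saturate_level, median_size, median_size, t))
}

# Sliding square median with replicate padding. Even window sizes use
# offsets -size/2 .. size/2 - 1 and the lower median, which keeps counts
# integer. Plain order-statistic implementation; fields are a few hundred
# pixels on a side so this is fast enough.
median_filter_square <- function(px, size = 8L) {
  size <- as.integer(size)
  stopifnot(size >= 1L)
  nr <- nrow(px); nc <- ncol(px)
  offs <- seq.int(-(size %/% 2), size - (size %/% 2) - 1L)
  k <- length(offs)^2
  stack <- matrix(0L, nr * nc, k)
  idx <- 1L
  for (dr in offs) {
    rr <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    for (dc in offs) {
      cc <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
      stack[, idx] <- px[rr, cc]
      idx <- idx + 1L
    }
  }
  lower_median <- (k + 1L) %/% 2L
  out <- apply(stack, 1L, function(v) sort.int(v, partial = lower_median)[lower_median])
  matrix(as.integer(out), nr, nc)
}
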