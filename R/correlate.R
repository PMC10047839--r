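#' Correlate per-spine NF and synaptic-marker amounts
#'
#' Joins the two per-spine quantification tables by spine id, removes
#' excluded spines, z-standardizes each variable within its experimental
#' round, pools the standardized rounds, and computes the Spearman rank
#' correlation with its p-value and interpretation band. This is the core
#' statistical contract of the pipeline: per-round standardization makes
#' the pooled rank correlation invariant to round-specific positive affine
#' distortions of the raw amounts.
#'
#' @param quants_nf,quants_marker Tibbles with columns `roi_id`,
#'   `round_id`, `amount`, and optionally `excluded` (as produced by
#'   [quantify_roi()] rows bound together).
#' @param exclusions Optional character vector of additional spine ids to
#'   exclude.
#' @param isoform,marker Labels copied into the result.
#' @param sd_type Passed to [standardize_by_round()].
#' @return List with `result` (one-row tibble: `isoform`, `marker`, `rho`,
#'   `p_value`, `n_spines`, `band`) and `scatter` (per-spine tibble of
#'   standardized amounts `z_nf`, `z_marker` for plotting).
#' @export
correlation_pipeline <- function(quants_nf, quants_marker,
                                 exclusions = character(0),
                                 isoform = "NF", marker = "marker",
                                 sd_type = "sample") {
  nf <- as.data.frame(quants_nf)
  mk <- as.data.frame(quants_marker)
  for (df in list(nf, mk))
    if (!all(c("roi_id", "round_id", "amount") %in% names(df)))
      stop("quantification tables need columns roi_id, round_id, amount")
  if (!"excluded" %in% names(nf)) nf$excluded <- FALSE
  if (!"excluded" %in% names(mk)) mk$excluded <- FALSE
  joined <- merge(nf[, c("roi_id", "round_id", "amount", "excluded")],
                  mk[, c("roi_id", "round_id", "amount", "excluded")],
                  by = c("roi_id", "round_id"), suffixes = c("_nf", "_marker"))
  joined <- joined[!(joined$excluded_nf | joined$excluded_marker |
                       joined$roi_id %in% exclusions), , drop = FALSE]
  if (nrow(joined) < 3)
    stop("fewer than 3 matched spines after exclusion")
  z_nf <- standardize_by_round(joined$amount_nf, joined$round_id,
                               sd_type = sd_type)
  z_marker <- standardize_by_round(joined$amount_marker, joined$round_id,
                                   sd_type = sd_type)
  keep <- !is.na(z_nf) & !is.na(z_marker)
  sp <- spearman_rank(z_nf[keep], z_marker[keep])
  list(result = tibble::tibble(isoform = isoform, marker = marker,
                               rho = sp$rho, p_value = sp$p_value,
                               n_spines = sp$n,
                               band = classify_band(sp$rho)),
       scatter = tibble::tibble(spine_id = joined$roi_id[keep],
                                round_id = joined$round_id[keep],
                                z_nf = z_nf[keep],
                                z_marker = z_marker[keep]))
}

#' Run the full quantification pipeline on a synthetic scene
#'
#' End-to-end driver used for validation against ground truth: builds the
#' scene, renders photon-count channels, offsets minima to zero, forms the
#' channel-appropriate second masks (4-count threshold for NF, Otsu for the
#' synaptic marker), flags and excludes spines crossed by bright axonal NF
#' signal, quantifies each spine on the intersection of its ROI with the
#' second mask, and correlates the standardized pooled amounts.
#'
#' @param config A [scene_config()].
#' @param min_counts NF background threshold (counts).
#' @param overlap_fraction,bright_quantile Passed to
#'   [flag_crossed_spines()].
#' @return List: `scene`, `channels`, `quants_nf`, `quants_marker`,
#'   `correlation` (as from [correlation_pipeline()]), `occupancy` (from
#'   [fraction_above_area()]), `flags`.
#' @export
run_spine_pipeline <- function(config, min_counts = 4L,
                               overlap_fraction = 0.1,
                               bright_quantile = 0.95) {
  scene <- build_scene(config)
  rendered <- render_channels(scene, channels = c("nf", "marker"))
  nf_img <- offset_min_to_zero(rendered$channels$nf)
  mk_img <- offset_min_to_zero(rendered$channels$marker)
  shape <- dim(nf_img$pixels)

  # saturate once; thresholding the saturated image equals second_mask()
  nf_sat <- saturate_bright_spots(nf_img)
  mk_sat <- saturate_bright_spots(mk_img)
  nf_second <- nf_sat$pixels >= min_counts
  mk_second <- mk_sat$pixels > otsu_threshold(mk_sat)

  # axon region: rendered filament tracks dilated to their drawn width
  axon_mask <- matrix(FALSE, shape[1], shape[2])
  for (ax in scene$axons)
    axon_mask[polyline_pixels(ax$polyline, shape[1], shape[2])] <- TRUE
  if (length(scene$axons) > 0) {
    w <- max(vapply(scene$axons, `[[`, numeric(1), "width_px"))
    brush <- EBImage::makeBrush(2L * ceiling(w) + 1L, "disc")
    axon_mask <- as.matrix(EBImage::dilate(EBImage::Image(axon_mask * 1),
                                           brush)) > 0
  }

  sp <- scene$spines
  spine_idx <- lapply(sp$polygon, rasterize_polygon_idx, shape = shape)

  bright <- nf_img$pixels >
    stats::quantile(nf_img$pixels, bright_quantile, type = 1, names = FALSE)
  axonal_bright <- axon_mask & bright
  flags <- vapply(spine_idx, function(idx) {
    length(idx) > 0 &&
      sum(axonal_bright[idx]) / length(idx) >= overlap_fraction
  }, logical(1))
  names(flags) <- sp$spine_id

  px_area <- (config$pixel_size_nm / 1000)^2
  quant_all <- function(img_sat, second) {
    px <- as_channel_pixels(img_sat)
    n <- integer(nrow(sp)); total <- numeric(nrow(sp))
    for (i in seq_len(nrow(sp))) {
      sel <- spine_idx[[i]][second[spine_idx[[i]]]]
      n[i] <- length(sel)
      total[i] <- sum(px[sel])
    }
    mean_int <- ifelse(n == 0, 0, total / pmax(n, 1))
    tibble::tibble(roi_id = sp$spine_id, n_pixels = n,
                   area_um2 = n * px_area, mean_intensity = mean_int,
                   amount = n * px_area * mean_int, round_id = sp$round_id,
                   excluded = unname(flags))
  }
  quants_nf <- quant_all(nf_sat, nf_second)
  quants_marker <- quant_all(mk_sat, mk_second)

  correlation <- correlation_pipeline(quants_nf, quants_marker)
  occupancy <- fraction_above_area(quants_nf)
  list(scene = scene, channels = rendered, quants_nf = quants_nf,
       quants_marker = quants_marker, correlation = correlation,
       occupancy = occupancy, flags = flags)
}
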