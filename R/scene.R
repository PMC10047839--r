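#' Configuration for a synthetic spine-imaging scene
#'
#' Describes one simulated field of view of cultured hippocampal neurons:
#' a few dendrite shafts carrying dendritic spines, thin axonal filament
#' tracks, and per-spine ground-truth neurofilament (NF) and synaptic-marker
#' amounts coupled by a Gaussian copula at a chosen Spearman correlation.
#' Rendering (see [render_channels()]) follows a photon-counting imaging
#' model: emitter densities blurred by Gaussian PSFs and read out with
#' Poisson noise over a low count background.
#'
#' @param field_shape Image shape in pixels `c(rows, cols)`.
#' @param pixel_size_nm Pixel size (default 30 nm, the STED acquisition
#'   convention).
#' @param n_spines Number of spines to place.
#' @param n_axon_tracks Number of background axon tracks routed through
#'   corridors between dendrites (never touching spines).
#' @param psf_fwhm_sted_nm,psf_fwhm_confocal_nm Isotropic Gaussian PSF
#'   FWHM per modality (sigma = FWHM / 2.355).
#' @param background_rate Mean background counts per pixel (Poisson).
#' @param axon_brightness Mean counts at an axonal filament core in the NF
#'   STED channel.
#' @param marginal_params Log-normal marginals for the true per-spine
#'   amounts: a list with elements `nf` and `marker`, each
#'   `c(meanlog, sdlog)`.
#' @param rho_spearman_true Target population Spearman correlation between
#'   NF and marker amounts, in `[-1, 1]`.
#' @param n_rounds Number of experimental rounds; each spine is assigned a
#'   round uniformly and each round gets its own multiplicative gain.
#' @param round_gain_range Interval the per-round gains are drawn from.
#' @param crossing_fraction Fraction of spines deliberately crossed by a
#'   bright axon track.
#' @param p_occupied Probability that a spine contains NF signal at all
#'   (1 = every spine, lower values emulate isoform-specific occupancy).
#' @param nf_fill If `TRUE`, an occupied spine's NF photons are spread
#'   uniformly over its head instead of concentrated in 1-5 puncta.
#' @param head_diameter_um,neck_length_um Spine head diameter and neck
#'   length ranges (uniform).
#' @param dendrite_radius_um Dendrite shaft half-width.
#' @param volume_brightness,axon_marker_brightness Mean emitter densities
#'   (counts/pixel before blur) for the confocal volume and axon-marker
#'   channels.
#' @param mixing_matrix 2 x 2 spectral bleed-through matrix applied by the
#'   forward model when simulating mixed channels (identity = no mixing).
#' @param seed Integer seed; identical configs produce bit-identical scenes.
#'
#' @return A `scene_config` list.
#' @export
scene_config <- function(field_shape = c(640L, 640L),
                         pixel_size_nm = 30,
                         n_spines = 100L,
                         n_axon_tracks = 4L,
                         psf_fwhm_sted_nm = 60,
                         psf_fwhm_confocal_nm = 250,
                         background_rate = 1.5,
                         axon_brightness = 12,
                         marginal_params = list(nf = c(meanlog = log(400), sdlog = 0.6),
                                                marker = c(meanlog = log(400), sdlog = 0.6)),
                         rho_spearman_true = 0.5,
                         n_rounds = 3L,
                         round_gain_range = c(0.7, 1.4),
                         crossing_fraction = 0.1,
                         p_occupied = 1,
                         nf_fill = FALSE,
                         head_diameter_um = c(0.3, 1),
                         neck_length_um = c(0.15, 0.45),
                         dendrite_radius_um = 0.25,
                         volume_brightness = 15,
                         axon_marker_brightness = 15,
                         mixing_matrix = diag(2),
                         seed = 1L) {
  cfg <- list(field_shape = as.integer(field_shape),
              pixel_size_nm = pixel_size_nm, n_spines = as.integer(n_spines),
              n_axon_tracks = as.integer(n_axon_tracks),
              psf_fwhm_sted_nm = psf_fwhm_sted_nm,
              psf_fwhm_confocal_nm = psf_fwhm_confocal_nm,
              background_rate = background_rate,
              axon_brightness = axon_brightness,
              marginal_params = marginal_params,
              rho_spearman_true = rho_spearman_true,
              n_rounds = as.integer(n_rounds),
              round_gain_range = round_gain_range,
              crossing_fraction = crossing_fraction,
              p_occupied = p_occupied, nf_fill = isTRUE(nf_fill),
              head_diameter_um = head_diameter_um,
              neck_length_um = neck_length_um,
              dendrite_radius_um = dendrite_radius_um,
              volume_brightness = volume_brightness,
              axon_marker_brightness = axon_marker_brightness,
              mixing_matrix = as.matrix(mixing_matrix),
              seed = as.integer(seed))
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  if (length(cfg$field_shape) != 2 || any(cfg$field_shape <= 0))
    stop("`field_shape` must be two positive integers")
  if (abs(cfg$rho_spearman_true) > 1)
    stop("invalid parameter: `rho_spearman_true` must lie in [-1, 1]")
  nonneg <- c(background_rate = cfg$background_rate,
              axon_brightness = cfg$axon_brightness,
              crossing_fraction = cfg$crossing_fraction,
              n_spines = cfg$n_spines, n_axon_tracks = cfg$n_axon_tracks)
  if (any(nonneg < 0))
    stop("invalid parameter: ", paste(names(nonneg)[nonneg < 0], collapse = ", "),
         " must be nonnegative")
  if (cfg$p_occupied < 0 || cfg$p_occupied > 1)
    stop("invalid parameter: `p_occupied` must be in [0, 1]")
  if (cfg$n_rounds < 1) stop("`n_rounds` must be >= 1")
  if (cfg$crossing_fraction > 1) stop("`crossing_fraction` must be <= 1")
  invisible(cfg)
}

#' Sample coupled (NF, marker) amount pairs
#'
#' Draws `n` pairs with log-normal marginals coupled by a Gaussian copula.
#' The latent Pearson correlation `r` is chosen from the requested Spearman
#' correlation via the bivariate-normal relation
#' `rho_S = (6 / pi) * asin(r / 2)`, i.e. `r = 2 * sin(pi * rho_S / 6)`,
#' so the population Spearman of the generator equals `rho_spearman_true`
#' (rank correlations are preserved by the monotone marginal transforms).
#' Uses the caller's RNG stream.
#'
#' @param n Number of pairs (>= 2).
#' @param marginal_params List with `nf` and `marker`, each
#'   `c(meanlog, sdlog)`.
#' @param rho_spearman_true Target Spearman correlation in `[-1, 1]`.
#' @return Tibble with strictly positive columns `nf_amount`,
#'   `marker_amount`.
#' @export
sample_amount_pairs <- function(n, marginal_params, rho_spearman_true) {
  if (abs(rho_spearman_true) > 1)
    stop("invalid parameter: `rho_spearman_true` must lie in [-1, 1]")
  if (n < 2) stop("`n` must be >= 2")
  r <- 2 * sin(pi * rho_spearman_true / 6)
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
  mp <- marginal_params
  tibble::tibble(
    nf_amount = stats::qlnorm(stats::pnorm(z1), mp$nf[[1]], mp$nf[[2]]),
    marker_amount = stats::qlnorm(stats::pnorm(z2), mp$marker[[1]],
                                  mp$marker[[2]]))
}

#' Build the geometry and ground truth of a synthetic scene
#'
#' Places horizontal dendrite shafts (smooth, gently undulating bands)
#' carrying `n_spines` spine polygons — a head of 0.3-1 um diameter on a
#' short neck protruding from the shaft — plus thin axonal polylines.
#' Background axon tracks run in corridors between dendrites; a fraction
#' `crossing_fraction` of spines additionally gets a bright axon routed
#' straight through its head. Each spine is assigned an experimental round
#' and a ground-truth (NF, marker) amount pair from
#' [sample_amount_pairs()]. The `crossed_by_axon` flag is computed
#' geometrically (axon polyline intersects the spine polygon).
#'
#' @param config A [scene_config()].
#' @return A `spine_scene`: `spines` tibble (ids, rounds, true amounts,
#'   flags, head geometry, polygons as a list-column), `axons` list of
#'   polylines, `shafts` (dendrite centerline parameters),
#'   `rho_spearman_true`, `mixing_matrix`, and `config`.
#' @export
build_scene <- function(config) {
  validate_scene_config(config)
  withr::with_seed(config$seed, build_scene_impl(config))
}

build_scene_impl <- function(cfg) {
  nr <- cfg$field_shape[1]; nc <- cfg$field_shape[2]
  px <- 1000 / cfg$pixel_size_nm
  r_head_max <- max(cfg$head_diameter_um) / 2 * px
  neck_max <- max(cfg$neck_length_um) * px
  dend_r <- cfg$dendrite_radius_um * px
  wobble <- 6
  extent <- neck_max + 2 * r_head_max
  margin_r <- ceiling(dend_r + wobble + extent + 4)
  spacing <- 2L * margin_r + 8L

  shaft_rows <- if (margin_r + 2 <= nr - margin_r - 3)
    seq(margin_r + 2, nr - margin_r - 3, by = spacing) else numeric(0)
  col_margin <- ceiling(r_head_max + 6)
  pitch <- ceiling(2 * r_head_max + 6)
  slot_cols <- if (col_margin <= nc - 1 - col_margin)
    seq(col_margin, nc - 1 - col_margin, by = pitch) else numeric(0)
  capacity <- length(shaft_rows) * length(slot_cols) * 2L
  if (cfg$n_spines > capacity)
    stop(sprintf(paste0("field too small to place requested geometry: ",
                        "%d spines requested, capacity %d"),
                 cfg$n_spines, capacity))

  shafts <- lapply(seq_along(shaft_rows), function(i)
    list(row0 = shaft_rows[i], amp = wobble * stats::runif(1, 0.5, 1),
         freq = sample(1:2, 1), phase = stats::runif(1, 0, 2 * pi),
         radius = dend_r))

  n <- cfg$n_spines
  spines_list <- list()
  if (n > 0) {
    combos <- expand.grid(shaft = seq_along(shaft_rows),
                          slot = seq_along(slot_cols), side = c(-1, 1))
    pick <- combos[sample.int(nrow(combos), n), , drop = FALSE]
    head_d <- stats::runif(n, cfg$head_diameter_um[1], cfg$head_diameter_um[2])
    neck_l <- stats::runif(n, cfg$neck_length_um[1], cfg$neck_length_um[2])
    spines_list <- lapply(seq_len(n), function(i) {
      sh <- shafts[[pick$shaft[i]]]
      side <- pick$side[i]
      c0 <- slot_cols[pick$slot[i]] + stats::runif(1, -2, 2)
      cl <- shaft_centerline(sh, c0, nc)
      r_head <- head_d[i] / 2 * px
      nl <- neck_l[i] * px
      base_r <- cl + side * (sh$radius - 1)
      head_r <- base_r + side * (nl + r_head)
      poly <- spine_polygon(base_r, c0, head_r, r_head, side)
      list(polygon = poly, head_r = head_r, head_c = c0,
           r_head_px = r_head, side = side, shaft = pick$shaft[i])
    })
  }

  # background axons in corridors midway between dendrite structures
  corridors <- if (length(shaft_rows) > 1)
    shaft_rows[-length(shaft_rows)] + spacing / 2 else numeric(0)
  edge_low <- shaft_rows[1] - margin_r - 4
  if (edge_low >= 6) corridors <- c(edge_low, corridors)
  edge_high <- shaft_rows[length(shaft_rows)] + margin_r + 4
  if (edge_high <= nr - 7) corridors <- c(corridors, edge_high)
  axons <- list()
  if (cfg$n_axon_tracks > 0 && length(corridors) > 0) {
    for (k in seq_len(cfg$n_axon_tracks)) {
      row0 <- corridors[((k - 1) %% length(corridors)) + 1]
      cols <- seq(2, nc - 3, by = 4)
      rows <- row0 + 2 * sin(2 * pi * cols / nc * sample(1:3, 1) +
                               stats::runif(1, 0, 2 * pi))
      rows <- pmin(pmax(rows, 3), nr - 4)
      axons[[length(axons) + 1]] <-
        list(id = sprintf("axon_bg_%02d", k), polyline = cbind(rows, cols),
             width_px = 2)
    }
  }

  # deliberately crossing axons through a chosen subset of spine heads
  n_cross <- round(cfg$crossing_fraction * n)
  cross_idx <- if (n_cross > 0) sample.int(n, n_cross) else integer(0)
  for (j in seq_along(cross_idx)) {
    sp <- spines_list[[cross_idx[j]]]
    # short, steep track: crosses this head but clears neighbouring spines
    ang <- sample(c(-1, 1), 1) * stats::runif(1, 0.35, 0.6)
    len <- sp$r_head_px + 14
    tt <- seq(-len, len, by = 2)
    rows <- sp$head_r + tt * sin(ang)
    cols <- sp$head_c + tt * cos(ang)
    keep <- rows >= 3 & rows <= nr - 4 & cols >= 2 & cols <= nc - 3
    axons[[length(axons) + 1]] <-
      list(id = sprintf("axon_cross_%02d", j),
           polyline = cbind(rows[keep], cols[keep]), width_px = 2)
  }

  crossed <- vapply(spines_list, function(sp)
    any(vapply(axons, function(ax)
      polyline_hits_polygon(ax$polyline, sp$polygon), logical(1))),
    logical(1))
  if (n == 0) crossed <- logical(0)

  amounts <- if (n >= 2)
    sample_amount_pairs(n, cfg$marginal_params, cfg$rho_spearman_true)
  else tibble::tibble(nf_amount = numeric(n) + 1, marker_amount = numeric(n) + 1)

  spines <- tibble::tibble(
    spine_id = sprintf("spine_%04d", seq_len(n)),
    round_id = paste0("r", sample.int(cfg$n_rounds, n, replace = TRUE)),
    true_nf_amount = amounts$nf_amount,
    true_marker_amount = amounts$marker_amount,
    crossed_by_axon = crossed,
    nf_present = stats::runif(n) < cfg$p_occupied,
    head_r = vapply(spines_list, `[[`, numeric(1), "head_r"),
    head_c = vapply(spines_list, `[[`, numeric(1), "head_c"),
    r_head_px = vapply(spines_list, `[[`, numeric(1), "r_head_px"),
    side = vapply(spines_list, `[[`, numeric(1), "side"),
    shaft = vapply(spines_list, function(s) as.integer(s$shaft), integer(1)),
    polygon = lapply(spines_list, `[[`, "polygon"))

  structure(list(config = cfg, spines = spines, axons = axons,
                 shafts = shafts,
                 rho_spearman_true = cfg$rho_spearman_true,
                 mixing_matrix = cfg$mixing_matrix),
            class = "spine_scene")
}

#' @export
print.spine_scene <- function(x, ...) {
  cat(sprintf(paste0("<spine_scene> %dx%d px, %d spines (%d crossed), ",
                     "%d axon tracks, %d rounds, rho_true = %.3g\n"),
              x$config$field_shape[1], x$config$field_shape[2],
              nrow(x$spines), sum(x$spines$crossed_by_axon),
              length(x$axons), x$config$n_rounds, x$rho_spearman_true))
  invisible(x)
}

shaft_centerline <- function(sh, cols, nc) {
  sh$row0 + sh$amp * sin(2 * pi * sh$freq * cols / nc + sh$phase)
}

# Spine outline: two vertical neck sides joined by a circular-arc head.
spine_polygon <- function(base_r, c0, head_r, r_head, side, wn = 2,
                          n_arc = 16) {
  wn <- min(wn, 0.9 * r_head)
  sq <- sqrt(r_head^2 - wn^2)
  th_r <- atan2(-side * sq / r_head, wn / r_head)
  th_l <- atan2(-side * sq / r_head, -wn / r_head)
  th_end <- if (side > 0) th_l + 2 * pi else th_l - 2 * pi
  th <- seq(th_r, th_end, length.out = n_arc)
  arc <- cbind(head_r + r_head * sin(th), c0 + r_head * cos(th))
  rbind(c(base_r, c0 - wn), c(base_r, c0 + wn), arc)
}

polyline_hits_polygon <- function(polyline, polygon) {
  # coarse bounding-box rejection, then dense sampling along the polyline
  if (max(polyline[, 1]) < min(polygon[, 1]) - 1 ||
      min(polyline[, 1]) > max(polygon[, 1]) + 1 ||
      max(polyline[, 2]) < min(polygon[, 2]) - 1 ||
      min(polyline[, 2]) > max(polygon[, 2]) + 1) return(FALSE)
  pts <- densify_polyline(polyline, step = 1)
  any(points_in_polygon(pts[, 1], pts[, 2], polygon))
}

densify_polyline <- function(polyline, step = 1) {
  segs <- lapply(seq_len(nrow(polyline) - 1), function(i) {
    a <- polyline[i, ]; b <- polyline[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    tt <- seq(0, 1, length.out = max(2, ceiling(len / step) + 1))
    cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
  })
  do.call(rbind, segs)
}

#' Convert a scene's geometry to a region-of-interest set
#'
#' Spine polygons become spine-labelled ROIs (carrying their round ids);
#' axon polylines are buffered to thin polygons and become axon-labelled
#' ROIs, standing in for the manual morphological segmentation performed on
#' real data.
#'
#' @param scene A `spine_scene`.
#' @return A [roi_set()].
#' @export
as_roi_set <- function(scene) {
  stopifnot(inherits(scene, "spine_scene"))
  nr <- scene$config$field_shape[1]; nc <- scene$config$field_shape[2]
  spine_rois <- lapply(seq_len(nrow(scene$spines)), function(i)
    list(id = scene$spines$spine_id[i], label = "spine",
         polygon = scene$spines$polygon[[i]],
         round = scene$spines$round_id[i]))
  axon_rois <- lapply(scene$axons, function(ax)
    list(id = ax$id, label = "axon",
         polygon = buffer_polyline(ax$polyline, ax$width_px, nr, nc),
         round = NA_character_))
  roi_set(c(spine_rois, axon_rois),
          image_id = sprintf("scene_%d", scene$config$seed))
}

# Offset a polyline by +/- w along its normals to get a ribbon polygon.
buffer_polyline <- function(polyline, w, nr, nc) {
  p <- polyline
  dup <- c(FALSE, rowSums(abs(diff(p))) == 0)
  p <- p[!dup, , drop = FALSE]
  m <- nrow(p)
  d <- rbind(p[2, ] - p[1, ],
             (p[pmin(seq_len(m) + 1, m), ] - p[pmax(seq_len(m) - 1, 1), ])[-c(1, m), , drop = FALSE],
             p[m, ] - p[m - 1, ])
  len <- sqrt(rowSums(d^2)); len[len == 0] <- 1
  nrm <- cbind(-d[, 2] / len, d[, 1] / len)
  up <- p + w * nrm
  dn <- p - w * nrm
  poly <- rbind(up, dn[m:1, , drop = FALSE])
  poly[, 1] <- pmin(pmax(poly[, 1], 0), nr - 1)
  poly[, 2] <- pmin(pmax(poly[, 2], 0), nc - 1)
  poly
}
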