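# Imaging model: emitter densities are laid out on the pixel grid, blurred
# with an isotropic Gaussian PSF (sigma = FWHM / 2.355), and read out as
# Poisson counts over a uniform background rate, matching photon-counting
# APD detection.

gaussian_psf_kernel <- function(sigma_px) {
  size <- 2L * ceiling(3 * sigma_px) + 1L
  k1 <- stats::dnorm(seq(-(size %/% 2), size %/% 2), sd = sigma_px)
  k1 <- k1 / sum(k1)
  outer(k1, k1)
}

# Separable shift-and-sum convolution with replicate boundary; for the
# small PSF kernels used here this is faster than FFT filtering.
blur_psf <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  size <- 2L * ceiling(3 * sigma_px) + 1L
  offs <- seq(-(size %/% 2), size %/% 2)
  k1 <- stats::dnorm(offs, sd = sigma_px)
  k1 <- k1 / sum(k1)
  nr <- nrow(mat); nc <- ncol(mat)
  tmp <- matrix(0, nr, nc)
  for (i in seq_along(offs)) {
    rows <- pmin(pmax(seq_len(nr) + offs[i], 1L), nr)
    tmp <- tmp + k1[i] * mat[rows, , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (i in seq_along(offs)) {
    cols <- pmin(pmax(seq_len(nc) + offs[i], 1L), nc)
    out <- out + k1[i] * tmp[, cols, drop = FALSE]
  }
  out
}

# Value at the core of a blurred 1-px-wide line of unit density: the centre
# column sum of the PSF kernel. Line densities are divided by this so that
# "brightness" parameters mean counts at the filament core after blurring.
line_core_gain <- function(sigma_px) {
  if (sigma_px <= 0) return(1)
  k <- gaussian_psf_kernel(sigma_px)
  sum(k[, (ncol(k) + 1L) %/% 2L])
}

polyline_pixels <- function(polyline, nr, nc, step = 0.4) {
  pts <- densify_polyline(polyline, step = step)
  r <- pmin(pmax(round(pts[, 1]), 0), nr - 1)
  c <- pmin(pmax(round(pts[, 2]), 0), nc - 1)
  unique(cbind(r + 1, c + 1))  # 1-based matrix indices
}

dendrite_mask <- function(scene) {
  nr <- scene$config$field_shape[1]; nc <- scene$config$field_shape[2]
  m <- matrix(FALSE, nr, nc)
  for (sh in scene$shafts) {
    cl <- shaft_centerline(sh, 0:(nc - 1), nc)
    lo <- max(1L, floor(min(cl) - sh$radius) + 1L)
    hi <- min(nr, ceiling(max(cl) + sh$radius) + 1L)
    if (lo > hi) next
    rows0 <- (lo:hi) - 1L
    m[lo:hi, ] <- m[lo:hi, ] | (abs(outer(rows0, cl, "-")) <= sh$radius)
  }
  m
}

disc_pixels <- function(center_r, center_c, radius, nr, nc) {
  r0 <- max(0, floor(center_r - radius)); r1 <- min(nr - 1, ceiling(center_r + radius))
  c0 <- max(0, floor(center_c - radius)); c1 <- min(nc - 1, ceiling(center_c + radius))
  rows <- r0:r1; cols <- c0:c1
  pr <- rep(rows, times = length(cols)); pc <- rep(cols, each = length(rows))
  keep <- (pr - center_r)^2 + (pc - center_c)^2 <= radius^2
  cbind(pr[keep] + 1, pc[keep] + 1)
}

#' Expected (noise-free) photon counts for each channel of a scene
#'
#' Deterministic given the scene: per-round gains and sub-resolution
#' emitter placements are drawn from a seed derived from the scene's.
#' Channels: confocal volume (uniform density over dendrite + spines),
#' confocal axon marker (along axon tracks), STED neurofilament (line
#' emitters along axons plus, per occupied spine, 1-5 point emitters whose
#' summed intensity equals `true_nf_amount * round_gain`), and STED
#' synaptic marker (one punctum per spine head of intensity
#' `true_marker_amount * round_gain`). Background is not included here.
#'
#' @param scene A `spine_scene` from [build_scene()].
#' @param channels Which channels to render (any subset of `"volume"`,
#'   `"axon_marker"`, `"nf"`, `"marker"`). Sub-resolution emitter
#'   placements are drawn identically regardless of the subset, so a
#'   channel's expected image does not depend on which other channels were
#'   requested.
#' @return List with `expected` (named list of matrices) and `gains`
#'   (tibble `round_id`, `gain`).
#' @export
render_expected <- function(scene, channels = c("volume", "axon_marker",
                                                "nf", "marker")) {
  stopifnot(inherits(scene, "spine_scene"))
  channels <- match.arg(channels, several.ok = TRUE)
  withr::with_seed(scene$config$seed + 1L,
                   render_expected_impl(scene, channels))
}

render_expected_impl <- function(scene, channels) {
  cfg <- scene$config
  nr <- cfg$field_shape[1]; nc <- cfg$field_shape[2]
  sigma_sted <- cfg$psf_fwhm_sted_nm / 2.355 / cfg$pixel_size_nm
  sigma_conf <- cfg$psf_fwhm_confocal_nm / 2.355 / cfg$pixel_size_nm
  want <- function(ch) ch %in% channels

  gains <- tibble::tibble(
    round_id = paste0("r", seq_len(cfg$n_rounds)),
    gain = stats::runif(cfg$n_rounds, cfg$round_gain_range[1],
                        cfg$round_gain_range[2]))
  gain_of <- stats::setNames(gains$gain, gains$round_id)

  zeros <- function() matrix(0, nr, nc)
  vol <- if (want("volume")) zeros() else NULL
  axm <- if (want("axon_marker")) zeros() else NULL
  nf <- if (want("nf")) zeros() else NULL
  mk <- if (want("marker")) zeros() else NULL
  if (want("volume")) vol[dendrite_mask(scene)] <- cfg$volume_brightness

  lg_sted <- line_core_gain(sigma_sted)
  lg_conf <- line_core_gain(sigma_conf)
  if (want("axon_marker") || want("nf")) {
    for (ax in scene$axons) {
      pix <- polyline_pixels(ax$polyline, nr, nc)
      if (want("axon_marker")) axm[pix] <- cfg$axon_marker_brightness / lg_conf
      if (want("nf")) nf[pix] <- cfg$axon_brightness / lg_sted
    }
  }

  sp <- scene$spines
  for (i in seq_len(nrow(sp))) {
    if (want("volume")) {
      idx <- rasterize_polygon_idx(sp$polygon[[i]], c(nr, nc))
      vol[idx] <- cfg$volume_brightness
    }
    g <- gain_of[[sp$round_id[i]]]
    # synaptic marker: one punctum per spine head (small placement jitter)
    pr <- min(max(round(sp$head_r[i] + stats::runif(1, -1, 1)), 0), nr - 1)
    pc <- min(max(round(sp$head_c[i] + stats::runif(1, -1, 1)), 0), nc - 1)
    if (want("marker"))
      mk[pr + 1, pc + 1] <- mk[pr + 1, pc + 1] + sp$true_marker_amount[i] * g
    if (!sp$nf_present[i]) next
    total <- sp$true_nf_amount[i] * g
    if (cfg$nf_fill) {
      if (want("nf")) {
        pix <- disc_pixels(sp$head_r[i], sp$head_c[i], sp$r_head_px[i],
                           nr, nc)
        nf[pix] <- nf[pix] + total / nrow(pix)
      }
    } else {
      npunc <- sample.int(5L, 1L)
      w <- stats::rexp(npunc); w <- w / sum(w)
      rad <- stats::runif(npunc, 0, 0.8 * sp$r_head_px[i])
      ang <- stats::runif(npunc, 0, 2 * pi)
      if (want("nf")) {
        qr <- pmin(pmax(round(sp$head_r[i] + rad * sin(ang)), 0), nr - 1)
        qc <- pmin(pmax(round(sp$head_c[i] + rad * cos(ang)), 0), nc - 1)
        for (q in seq_len(npunc))
          nf[qr[q] + 1, qc[q] + 1] <- nf[qr[q] + 1, qc[q] + 1] + total * w[q]
      }
    }
  }

  expected <- list()
  if (want("volume")) expected$volume <- blur_psf(vol, sigma_conf)
  if (want("axon_marker")) expected$axon_marker <- blur_psf(axm, sigma_conf)
  if (want("nf")) expected$nf <- blur_psf(nf, sigma_sted)
  if (want("marker")) expected$marker <- blur_psf(mk, sigma_sted)
  list(expected = expected, gains = gains)
}

#' Render the photon-count channels of a scene
#'
#' Draws each channel as Poisson(expected counts + background rate), stored
#' as nonnegative integer counts, and wraps them as [channel_image()]s with
#' the appropriate modality. Identical scenes yield bit-identical channels.
#'
#' @inheritParams render_expected
#' @param scene A `spine_scene` from [build_scene()].
#' @return List with `channels` (named list of [channel_image()]s:
#'   `volume`, `axon_marker`, `nf`, `marker`), `gains`, and `expected`.
#' @export
render_channels <- function(scene, channels = c("volume", "axon_marker",
                                                "nf", "marker")) {
  channels <- match.arg(channels, several.ok = TRUE)
  re <- render_expected(scene, channels)
  cfg <- scene$config
  nr <- cfg$field_shape[1]; nc <- cfg$field_shape[2]
  image_id <- sprintf("scene_%d", cfg$seed)
  modal <- c(volume = "confocal", axon_marker = "confocal",
             nf = "STED", marker = "STED")
  # per-channel seeds so a channel's noise realization is independent of
  # which other channels were requested
  imgs <- lapply(stats::setNames(names(re$expected), names(re$expected)),
                 function(ch) {
                   off <- match(ch, names(modal))
                   withr::with_seed(cfg$seed + 2L + off, {
                     lambda <- re$expected[[ch]] + cfg$background_rate
                     counts <- matrix(stats::rpois(nr * nc, lambda), nr, nc)
                     channel_image(counts, channel = ch,
                                   modality = modal[[ch]],
                                   pixel_size_nm = cfg$pixel_size_nm,
                                   image_id = image_id)
                   })
                 })
  list(channels = imgs, gains = re$gains, expected = re$expected)
}
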