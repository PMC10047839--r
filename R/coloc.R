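#' Non-zero-pixel Pearson colocalization
#'
#' Pearson correlation of two photon-count channels restricted to masked
#' pixels with non-zero intensity — the colocalization measure for pairs of
#' immunolabels. Both images should be offset so their minimum is 0 first
#' (see [offset_min_to_zero()]). Two inclusion policies are supported:
#' `"either_nonzero"` keeps a pixel when at least one channel is non-zero
#' there (the default; retains anticorrelated signal), `"both_nonzero"`
#' requires both.
#'
#' @param a,b [channel_image()]s or integer matrices of the same shape.
#' @param mask [pixel_mask()] or logical matrix restricting the comparison
#'   (e.g. a spine, axon, or cell-level mask). `NULL` uses the whole image.
#' @param policy Pixel inclusion policy.
#' @param compartment Label copied into the result.
#' @return One-row [tibble::tibble()]: `image_id`, `compartment`, `r`,
#'   `n_pixels_used`, `inclusion_policy`, `reliable`. When fewer than 3
#'   qualifying pixels remain or either vector has zero variance, `r` is
#'   `NA` and `reliable` is `FALSE` rather than returning a number.
#' @export
nonzero_pearson <- function(a, b, mask = NULL,
                            policy = c("either_nonzero", "both_nonzero"),
                            compartment = NA_character_) {
  policy <- match.arg(policy)
  pa <- as_channel_pixels(a); pb <- as_channel_pixels(b)
  check_same_shape(pa, pb, "channels")
  m <- if (is.null(mask)) matrix(TRUE, nrow(pa), ncol(pa))
       else as_mask_pixels(mask)
  check_same_shape(pa, m, "channel and mask")
  keep <- if (policy == "either_nonzero") m & (pa > 0 | pb > 0)
          else m & (pa > 0 & pb > 0)
  x <- as.numeric(pa[keep]); y <- as.numeric(pb[keep])
  n <- length(x)
  image_id <- if (inherits(a, "channel_image")) a$image_id else NA_character_
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(image_id = image_id, compartment = compartment,
                          r = NA_real_, n_pixels_used = n,
                          inclusion_policy = policy, reliable = FALSE))
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * stats::sd(x) * stats::sd(y))
  tibble::tibble(image_id = image_id, compartment = compartment, r = r,
                 n_pixels_used = n, inclusion_policy = policy,
                 reliable = TRUE)
}

#' Summarize per-image colocalization results
#'
#' Per-group mean of the per-image Pearson coefficients and the standard
#' error of that mean (SEM = sd / sqrt(n_images); `NA` for single-image
#' groups). Unreliable results are dropped; empty groups are omitted with a
#' warning.
#'
#' @param results Tibble of [nonzero_pearson()] rows, one per image.
#' @param group_by Character vector of grouping columns (default
#'   `"compartment"`; add e.g. an isoform-pair column).
#' @return Tibble with columns `group_by`, `mean_r`, `sem`, `n_images`.
#' @export
summarize_coloc <- function(results, group_by = "compartment") {
  res <- results[results$reliable %in% TRUE, , drop = FALSE]
  if (nrow(res) < nrow(results))
    warning(nrow(results) - nrow(res), " unreliable result(s) dropped")
  if (nrow(res) == 0) {
    warning("no reliable colocalization results")
    return(tibble::tibble())
  }
  out <- dplyr::summarise(
    dplyr::group_by(res, dplyr::across(dplyr::all_of(group_by))),
    mean_r = mean(.data$r),
    sem = if (dplyr::n() > 1) stats::sd(.data$r) / sqrt(dplyr::n())
          else NA_real_,
    n_images = dplyr::n(), .groups = "drop")
  out
}
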