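#' Forward spectral mixing of two source channels
#'
#' Applies a 2 x 2 nonnegative mixing matrix per pixel:
#' `mixed = M %*% c(a, b)`, rounded back to integer counts. This is the
#' forward model of dye bleed-through between two detection channels; with
#' the identity matrix the outputs equal the inputs.
#'
#' @param source_a,source_b [channel_image()]s or matrices, same shape.
#' @param mixing_matrix 2 x 2 nonnegative matrix; no column may be all zero.
#' @return List of two mixed images (same type as inputs).
#' @export
apply_spectral_mixing <- function(source_a, source_b, mixing_matrix) {
  M <- as.matrix(mixing_matrix)
  if (!identical(dim(M), c(2L, 2L)) || any(M < 0))
    stop("`mixing_matrix` must be a 2x2 nonnegative matrix")
  if (all(M == 0))
    stop("`mixing_matrix` must have at least one non-zero column")
  pa <- as_channel_pixels(source_a); pb <- as_channel_pixels(source_b)
  check_same_shape(pa, pb, "source channels")
  m1 <- round(M[1, 1] * pa + M[1, 2] * pb)
  m2 <- round(M[2, 1] * pa + M[2, 2] * pb)
  storage.mode(m1) <- "integer"; storage.mode(m2) <- "integer"
  list(with_pixels(source_a, m1), with_pixels(source_b, m2))
}

#' Estimate the mixing matrix from single-color reference samples
#'
#' Each dye is imaged alone in both detection channels; its column of the
#' mixing matrix is the mean channel response over foreground pixels
#' (Otsu mask on the dye's dominant channel), normalized to sum to 1.
#'
#' @param single_color_a,single_color_b Each a list of two
#'   [channel_image()]s/matrices: the dye's signal in detection channel 1
#'   and channel 2.
#' @return List of class `mixing_estimate`: `matrix` (columns sum to 1),
#'   `condition_number`, `source_images`.
#' @export
estimate_mixing <- function(single_color_a, single_color_b) {
  col_for <- function(pair) {
    p1 <- as_channel_pixels(pair[[1]]); p2 <- as_channel_pixels(pair[[2]])
    check_same_shape(p1, p2, "reference channels")
    dominant <- if (sum(p1) >= sum(p2)) p1 else p2
    fg <- dominant > otsu_threshold(dominant)
    if (!any(fg)) stop("no foreground pixels in single-color reference")
    v <- c(mean(p1[fg]), mean(p2[fg]))
    v / sum(v)
  }
  M <- cbind(col_for(single_color_a), col_for(single_color_b))
  if (abs(det(M)) < .Machine$double.eps)
    stop("singular mixing matrix: the two references are indistinguishable")
  cond <- kappa(M, exact = TRUE)
  if (cond > 1e3)
    warning(sprintf("mixing matrix is near-singular (condition %.3g)", cond))
  ids <- function(pair) vapply(pair, function(im)
    if (inherits(im, "channel_image")) im$image_id else NA_character_,
    character(1))
  structure(list(matrix = M, condition_number = cond,
                 source_images = c(ids(single_color_a), ids(single_color_b))),
            class = "mixing_estimate")
}

#' @export
print.mixing_estimate <- function(x, ...) {
  cat("<mixing_estimate> condition number", format(x$condition_number), "\n")
  print(round(x$matrix, 4))
  invisible(x)
}

#' Linear spectral unmixing of two detection channels
#'
#' Solves, per pixel, the nonnegative least-squares problem
#' `min ||M s - m||` over `s >= 0` (closed form for the 2 x 2 case: the
#' unconstrained solve when it is nonnegative, otherwise the better of the
#' two single-dye boundary solutions). Outputs are rounded, clamped at 0,
#' and stored as integer counts so they remain valid input for
#' count-based thresholding. With the identity matrix the output equals the
#' input.
#'
#' @param mixed_1,mixed_2 Mixed detection-channel images, same shape.
#' @param M A `mixing_estimate` or plain 2 x 2 matrix (well-conditioned).
#' @return List of two unmixed images (same type as inputs).
#' @export
unmix <- function(mixed_1, mixed_2, M) {
  if (inherits(M, "mixing_estimate")) M <- M$matrix
  M <- as.matrix(M)
  if (!identical(dim(M), c(2L, 2L))) stop("`M` must be 2x2")
  if (abs(det(M)) < .Machine$double.eps) stop("`M` is singular")
  p1 <- as_channel_pixels(mixed_1); p2 <- as_channel_pixels(mixed_2)
  check_same_shape(p1, p2, "mixed channels")
  m1 <- as.numeric(p1); m2 <- as.numeric(p2)
  Minv <- solve(M)
  s1 <- Minv[1, 1] * m1 + Minv[1, 2] * m2
  s2 <- Minv[2, 1] * m1 + Minv[2, 2] * m2
  bad <- s1 < 0 | s2 < 0
  if (any(bad)) {
    # boundary candidates: all signal assigned to one dye
    a1 <- pmax(0, (M[1, 1] * m1[bad] + M[2, 1] * m2[bad]) / sum(M[, 1]^2))
    a2 <- pmax(0, (M[1, 2] * m1[bad] + M[2, 2] * m2[bad]) / sum(M[, 2]^2))
    r1 <- (m1[bad] - M[1, 1] * a1)^2 + (m2[bad] - M[2, 1] * a1)^2
    r2 <- (m1[bad] - M[1, 2] * a2)^2 + (m2[bad] - M[2, 2] * a2)^2
    use1 <- r1 <= r2
    s1[bad] <- ifelse(use1, a1, 0)
    s2[bad] <- ifelse(use1, 0, a2)
  }
  shape <- dim(p1)
  u1 <- matrix(as.integer(pmax(0, round(s1))), shape[1], shape[2])
  u2 <- matrix(as.integer(pmax(0, round(s2))), shape[1], shape[2])
  list(with_pixels(mixed_1, u1), with_pixels(mixed_2, u2))
}
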