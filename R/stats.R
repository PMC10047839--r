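#' Standardize values by experimental round
#'
#' Computes `z = (x - mu_round) / sigma_round` within each round, the
#' standardization applied before pooling rounds, so that round-specific
#' gain and offset differences (different stainings, laser alignment,
#' detector settings) cancel. `sigma` is the sample (n-1) standard
#' deviation by default. Rounds with fewer than 2 values or zero variance
#' are dropped with a warning (their z-scores are `NA`).
#'
#' @param values Numeric vector of per-spine amounts.
#' @param rounds Vector of round identifiers, same length.
#' @param sd_type `"sample"` (n-1 denominator) or `"population"` (n).
#' @return Numeric vector of z-scores (`NA` for dropped rounds).
#' @export
standardize_by_round <- function(values, rounds,
                                 sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(values) != length(rounds))
    stop("`values` and `rounds` must have the same length")
  z <- rep(NA_real_, length(values))
  dropped <- character(0)
  for (r in unique(rounds)) {
    idx <- which(rounds == r)
    x <- values[idx]
    if (length(x) < 2) { dropped <- c(dropped, r); next }
    s <- stats::sd(x)
    if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
    if (!is.finite(s) || s == 0) { dropped <- c(dropped, r); next }
    z[idx] <- (x - mean(x)) / s
  }
  if (length(dropped) > 0)
    warning("dropped round(s) with < 2 values or zero variance: ",
            paste(dropped, collapse = ", "))
  if (all(is.na(z))) stop("all rounds dropped; nothing to standardize")
  z
}

#' Spearman rank correlation with p-value
#'
#' Pearson correlation of mid-ranks (average ranks on ties). The two-sided
#' p-value uses the exact permutation distribution over all `n!` orderings
#' for `n <= 9`, and the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' otherwise.
#'
#' @param x,y Paired numeric vectors, `n >= 3`, neither constant.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_rank <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have the same length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired values")
  if (anyNA(x) || anyNA(y)) stop("NA values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Spearman correlation undefined")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- max(-1, min(1, rank_pearson(rx, ry)))  # guard rounding at +/-1
  p <- if (n <= 9) {
    perms <- all_permutations(n)
    ry_perm <- matrix(ry[perms], nrow(perms), n)
    cross <- as.numeric(ry_perm %*% rx)
    rho_perm <- (cross - n * mean(rx) * mean(ry)) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    if (abs(rho) >= 1) 0 else 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

rank_pearson <- function(rx, ry) {
  n <- length(rx)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    ((n - 1) * stats::sd(rx) * stats::sd(ry))
}

# All permutations of 1..n as an n! x n matrix, built iteratively.
all_permutations <- function(n) {
  p <- matrix(1L, 1, 1)
  for (k in 2:n) {
    blocks <- lapply(seq_len(k), function(pos) {
      if (pos == 1) cbind(k, p)
      else if (pos == k) cbind(p, k)
      else cbind(p[, seq_len(pos - 1), drop = FALSE], k,
                 p[, pos:(k - 1), drop = FALSE])
    })
    p <- do.call(rbind, blocks)
  }
  p
}

#' Interpretation band for a Spearman coefficient
#'
#' The conventional interpretation applied to `|rho|`: below 0.3
#' negligible, 0.3-0.5 low, 0.5-0.7 moderate, 0.7 and above high.
#'
#' @param rho Numeric vector with `|rho| <= 1`.
#' @return Character vector of bands.
#' @export
classify_band <- function(rho) {
  if (anyNA(rho) || any(abs(rho) > 1)) stop("`rho` must lie in [-1, 1]")
  as.character(cut(abs(rho), breaks = c(-Inf, 0.3, 0.5, 0.7, Inf),
                   labels = c("negligible", "low", "moderate", "high"),
                   right = FALSE))
}
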