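test_that("nonzero_pearson recovers perfect and inverted correlation", {
  withr::with_seed(8, a <- random_count_image(10, 10, lambda = 5))
  r_self <- nonzero_pearson(a, a)
  expect_equal(r_self$r, 1, tolerance = 1e-12)
  b <- max(a) + 1L - a  # c - a for constant c, all pixels nonzero
  expect_equal(nonzero_pearson(a, b)$r, -1, tolerance = 1e-12)
})

test_that("nonzero_pearson matches the direct covariance formula", {
  a <- make_counts(c(3, 0, 5, 2, 0, 9, 1, 4, 0, 6, 2, 8, 0, 1, 7, 3, 2, 0,
                     4, 5, 6, 1, 0, 2, 9), 5, 5)
  b <- make_counts(c(1, 2, 0, 4, 0, 3, 6, 0, 2, 8, 1, 0, 5, 2, 3, 0, 7, 1,
                     2, 0, 4, 6, 3, 0, 5), 5, 5)
  for (policy in c("either_nonzero", "both_nonzero")) {
    res <- nonzero_pearson(a, b, policy = policy)
    keep <- if (policy == "either_nonzero") a > 0 | b > 0 else a > 0 & b > 0
    x <- a[keep]; y <- b[keep]
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(res$r, oracle, tolerance = 1e-12)
    expect_equal(res$n_pixels_used, sum(keep))
  }
  # random instances against stats::cor on the filtered vectors
  withr::with_seed(30, {
    for (i in 1:100) {
      a <- random_count_image(8, 8, lambda = 2)
      b <- random_count_image(8, 8, lambda = 2)
      keep <- a > 0 | b > 0
      if (sum(keep) < 3 || sd(a[keep]) == 0 || sd(b[keep]) == 0) next
      expect_equal(nonzero_pearson(a, b)$r, cor(a[keep], b[keep]),
                   tolerance = 1e-12)
    }
  })
})

test_that("nonzero_pearson signals unreliable results instead of numbers", {
  a <- make_counts(c(1, 0, 0, 0), 2, 2)
  b <- make_counts(c(2, 0, 0, 0), 2, 2)
  res <- nonzero_pearson(a, b)  # one qualifying pixel
  expect_false(res$reliable)
  expect_true(is.na(res$r))
  # zero variance case
  a2 <- make_counts(c(3, 3, 3, 3), 2, 2)
  b2 <- make_counts(c(1, 2, 3, 4), 2, 2)
  expect_false(nonzero_pearson(a2, b2)$reliable)
})

test_that("nonzero_pearson is symmetric and affine-invariant on the pixel set", {
  withr::with_seed(14, {
    a <- random_count_image(12, 12, lambda = 4)
    b <- random_count_image(12, 12, lambda = 4)
  })
  mask <- matrix(TRUE, 12, 12)
  r_ab <- nonzero_pearson(a, b, mask, policy = "both_nonzero")$r
  r_ba <- nonzero_pearson(b, a, mask, policy = "both_nonzero")$r
  expect_equal(r_ab, r_ba, tolerance = 1e-12)
  # positive rescaling of one channel on the same pixel set
  r_scaled <- nonzero_pearson(a * 3L, b, mask, policy = "both_nonzero")$r
  expect_equal(r_scaled, r_ab, tolerance = 1e-12)
})

test_that("summarize_coloc averages per-image r with SEM", {
  res <- tibble::tibble(image_id = c("i1", "i2", "i3"),
                        compartment = "spine", r = c(0.2, 0.4, 0.6),
                        n_pixels_used = 100, inclusion_policy = "either_nonzero",
                        reliable = TRUE)
  s <- summarize_coloc(res)
  expect_equal(s$mean_r, 0.4)
  expect_equal(s$sem, sd(c(0.2, 0.4, 0.6)) / sqrt(3))
  expect_equal(s$sem, 0.11547, tolerance = 1e-4)
  # single image: SEM not available; identical r: SEM 0
  expect_true(is.na(summarize_coloc(res[1, ])$sem))
  res$r <- 0.3
  expect_equal(summarize_coloc(res)$sem, 0)
})

test_that("apply_spectral_mixing implements the per-pixel matrix product", {
  withr::with_seed(17, {
    a <- random_count_image(9, 9, lambda = 10)
    b <- random_count_image(9, 9, lambda = 10)
  })
  id <- apply_spectral_mixing(a, b, diag(2))
  expect_identical(id[[1]], a)
  expect_identical(id[[2]], b)
  both_a <- apply_spectral_mixing(a, b, rbind(c(1, 0), c(1, 0)))
  expect_identical(both_a[[1]], a)
  expect_identical(both_a[[2]], a)
  M <- rbind(c(0.9, 0.2), c(0.1, 0.8))
  mixed <- apply_spectral_mixing(a, b, M)
  # per-pixel 2x2 multiplication oracle (integer output rounds the product,
  # so each pixel sits within half a count of it)
  for (idx in seq_len(81)) {
    expected <- M %*% c(a[idx], b[idx])
    expect_lte(max(abs(c(mixed[[1]][idx], mixed[[2]][idx]) - expected)),
               0.5 + 1e-9)
  }
  expect_error(apply_spectral_mixing(a, b[1:5, 1:5], M), "shape")
  expect_error(apply_spectral_mixing(a, b, rbind(c(1, 0), c(-1, 0))),
               "nonnegative")
})

test_that("estimate_mixing recovers reference columns and permutes on swap", {
  withr::with_seed(23, {
    src <- matrix(0L, 60, 60)
    src[20:40, 20:40] <- rpois(441, 80)
    M <- rbind(c(0.85, 0.15), c(0.15, 0.85))
    ref_a <- apply_spectral_mixing(src, matrix(0L, 60, 60), M)
    ref_b_pair <- apply_spectral_mixing(matrix(0L, 60, 60), src, M)
  })
  est <- estimate_mixing(ref_a, ref_b_pair)
  expect_equal(est$matrix, M, tolerance = 0.02)
  expect_equal(colSums(est$matrix), c(1, 1), tolerance = 1e-12)
  swapped <- estimate_mixing(ref_b_pair, ref_a)
  expect_equal(swapped$matrix, est$matrix[, 2:1], tolerance = 1e-12)
  # perfectly separated dyes give the identity
  pure_a <- list(src, matrix(0L, 60, 60))
  pure_b <- list(matrix(0L, 60, 60), src)
  expect_equal(estimate_mixing(pure_a, pure_b)$matrix, diag(2))
})

test_that("unmix inverts noiseless forward mixing within rounding", {
  withr::with_seed(31, {
    a <- random_count_image(40, 40, lambda = 30)
    b <- random_count_image(40, 40, lambda = 30)
  })
  M <- rbind(c(0.9, 0.2), c(0.1, 0.8))
  mixed <- apply_spectral_mixing(a, b, M)
  rec <- unmix(mixed[[1]], mixed[[2]], M)
  expect_lte(max(abs(rec[[1]] - a)), 1)
  expect_lte(max(abs(rec[[2]] - b)), 1)
  # identity leaves input unchanged; remixing reproduces the mixed data
  expect_identical(unmix(a, b, diag(2)), list(a, b))
  remix <- apply_spectral_mixing(rec[[1]], rec[[2]], M)
  expect_lte(max(abs(remix[[1]] - mixed[[1]])), 1)
  expect_lte(max(abs(remix[[2]] - mixed[[2]])), 1)
  expect_true(all(rec[[1]] >= 0) && all(rec[[2]] >= 0))
})

test_that("unmixing lowers colocalization of spatially disjoint sources", {
  M <- rbind(c(0.8, 0.25), c(0.2, 0.75))
  worse <- 0
  for (seed in 1:10) {
    withr::with_seed(seed, {
      a <- matrix(0L, 50, 50); a[5:20, 5:45] <- rpois(16 * 41, 40)
      b <- matrix(0L, 50, 50); b[30:45, 5:45] <- rpois(16 * 41, 40)
    })
    mixed <- apply_spectral_mixing(a, b, M)
    r_before <- nonzero_pearson(mixed[[1]], mixed[[2]])$r
    rec <- unmix(mixed[[1]], mixed[[2]], M)
    r_after <- nonzero_pearson(rec[[1]], rec[[2]])$r
    if (r_after < r_before) worse <- worse + 1
  }
  expect_equal(worse, 10)
})
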