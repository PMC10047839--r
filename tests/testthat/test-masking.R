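test_that("otsu_threshold matches exhaustive between-class-variance search", {
  withr::with_seed(42, {
    for (i in 1:50) {
      px <- matrix(sample.int(256, 400, replace = TRUE) - 1L, 20, 20)
      expect_identical(otsu_threshold(px), otsu_bruteforce(px))
    }
  })
})

test_that("otsu_threshold separates a perfect bimodal image and rejects a constant one", {
  px <- make_counts(rep(c(0, 10), each = 50), 10, 10)
  t <- otsu_threshold(px)
  expect_true(t >= 0 && t < 10)
  expect_equal(sum(px > t), 50)
  expect_error(otsu_threshold(matrix(3L, 4, 4)), "degenerate")
})

test_that("saturate_bright_spots clips only the extreme tail", {
  expect_identical(saturate_bright_spots(matrix(5L, 10, 10)),
                   matrix(5L, 10, 10))
  px <- make_counts(c(rep(0, 10000), 1e6), 10001, 1)
  out <- saturate_bright_spots(px, tail_fraction = 1e-4)
  # type-1 quantile of the known histogram: the 99.99th percentile is 0
  expect_equal(max(out), as.integer(quantile(px, 1 - 1e-4, type = 1)))
  expect_equal(sum(out != px), 1)
  withr::with_seed(7, {
    px <- random_count_image(50, 50, lambda = 3)
    out <- saturate_bright_spots(px, tail_fraction = 0.01)
    expect_lte(max(out), max(px))
    expect_lte(sum(out != px), ceiling(0.01 * length(px)))
  })
})

test_that("count_threshold_mask is inclusive at the boundary", {
  m <- count_threshold_mask(make_counts(c(3, 4, 5), 1, 3), min_counts = 4)
  expect_identical(as.vector(m$pixels), c(FALSE, TRUE, TRUE))
  expect_false(any(count_threshold_mask(matrix(0L, 4, 4))$pixels))
  expect_true(all(count_threshold_mask(matrix(0L, 4, 4), 0L)$pixels))
})

test_that("rasterize_roi uses pixel centres with the even-odd rule", {
  # rectangle spanning pixel centres rows 2..5, cols 3..10
  rect <- square_polygon(1.5, 5.5, 2.5, 10.5)
  m <- rasterize_roi(rect, c(20, 20))
  expect_equal(sum(m$pixels), 32)
  expect_true(all(which(m$pixels, arr.ind = TRUE)[, 1] %in% 3:6))  # 1-based
  # sliver covering no centres is a legal empty mask
  sliver <- rbind(c(2.1, 2.1), c(2.4, 2.2), c(2.2, 2.4))
  expect_equal(sum(rasterize_roi(sliver, c(10, 10))$pixels), 0)
  expect_match(rasterize_roi(sliver, c(10, 10))$source, "empty")
  expect_error(rasterize_roi(square_polygon(-5, 5, 0, 5), c(10, 10)),
               "outside")
})

test_that("rasterized right-triangle area approximates the analytic area", {
  tri <- rbind(c(10, 10), c(10, 70), c(50, 10))
  m <- rasterize_roi(tri, c(100, 100))
  analytic <- 0.5 * 60 * 40
  perimeter <- 60 + 40 + sqrt(60^2 + 40^2)
  expect_lt(abs(sum(m$pixels) - analytic), perimeter)
})

test_that("second_mask composes saturation and thresholding", {
  withr::with_seed(11, px <- random_count_image(40, 40, lambda = 2))
  px[1:5, 1:5] <- 60L
  for (kind in c("counts", "otsu")) {
    m <- second_mask(px, kind)
    sat <- saturate_bright_spots(px)
    ref <- if (kind == "counts") sat >= 4 else sat > otsu_threshold(sat)
    expect_identical(m$pixels, ref)
    expect_match(m$source, "saturate")
  }
  expect_false(any(second_mask(matrix(0L, 8, 8), "counts")$pixels))
})

test_that("spine_analysis_mask is a commutative intersection bounded by both inputs", {
  withr::with_seed(3, {
    a <- pixel_mask(matrix(runif(100) > 0.5, 10, 10), "a")
    b <- pixel_mask(matrix(runif(100) > 0.3, 10, 10), "b")
  })
  full <- pixel_mask(matrix(TRUE, 10, 10), "full")
  empty <- pixel_mask(matrix(FALSE, 10, 10), "empty")
  expect_identical(spine_analysis_mask(a, full)$pixels, a$pixels)
  expect_false(any(spine_analysis_mask(a, empty)$pixels))
  ab <- spine_analysis_mask(a, b)$pixels
  expect_identical(ab, spine_analysis_mask(b, a)$pixels)
  expect_true(all(which(ab) %in% which(a$pixels)))
  expect_true(all(which(ab) %in% which(b$pixels)))
  expect_error(spine_analysis_mask(a, pixel_mask(matrix(TRUE, 5, 5), "x")),
               "shape")
})

test_that("cell_level_mask recovers a bright cell body on dark background", {
  withr::with_seed(5, {
    px <- matrix(rpois(96 * 96, 0.5), 96, 96)
    px[30:70, 25:60] <- px[30:70, 25:60] + rpois(41 * 36, 30)
  })
  m <- cell_level_mask(px)
  truth <- matrix(FALSE, 96, 96); truth[30:70, 25:60] <- TRUE
  agreement <- mean(m$pixels == truth)
  expect_gt(agreement, 0.95)
  expect_error(cell_level_mask(matrix(2L, 10, 10)), "degenerate")
  # documented three-step composition
  clipped <- px; clip <- as.integer(floor(0.9 * max(px)))
  clipped[clipped > clip] <- clip
  med <- stedspine:::median_filter_square(clipped, 8L)
  expect_identical(m$pixels, med > otsu_threshold(med))
})

test_that("flag_crossed_spines flags constructed crossings only", {
  shape <- c(64, 64)
  spine_a <- square_polygon(9.5, 20.5, 9.5, 20.5)    # crossed
  spine_b <- square_polygon(39.5, 50.5, 39.5, 50.5)  # clear
  rois <- roi_set(list(
    list(id = "sa", label = "spine", polygon = spine_a),
    list(id = "sb", label = "spine", polygon = spine_b),
    list(id = "ax", label = "axon",
         polygon = square_polygon(13.5, 16.5, 0.5, 62.5))))
  nf <- matrix(1L, shape[1], shape[2])
  nf[15:17, ] <- 40L  # bright filament through spine_a
  flags <- flag_crossed_spines(rois, nf, rois)
  expect_identical(unname(flags), c(TRUE, FALSE))
  # no axon overlap anywhere -> no flags
  rois2 <- roi_set(list(
    list(id = "sa", label = "spine", polygon = spine_a),
    list(id = "ax", label = "axon",
         polygon = square_polygon(55.5, 58.5, 0.5, 62.5))))
  expect_false(any(flag_crossed_spines(rois2, nf, rois2)))
})

test_that("masks are idempotent under their defining threshold", {
  withr::with_seed(9, px <- random_count_image(30, 30, lambda = 6))
  m1 <- count_threshold_mask(px, 4)
  masked <- px; masked[!m1$pixels] <- 0L
  expect_identical(count_threshold_mask(masked, 4)$pixels, m1$pixels)
})
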