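make_quants <- function(ids, rounds, amounts, excluded = FALSE) {
  tibble::tibble(roi_id = ids, round_id = rounds, amount = amounts,
                 excluded = excluded)
}

test_that("correlation_pipeline recovers degenerate couplings", {
  withr::with_seed(61, {
    n <- 60
    ids <- sprintf("s%03d", 1:n)
    rounds <- rep(c("r1", "r2", "r3"), length.out = n)
    amounts <- rlnorm(n, log(300), 0.5)
  })
  nf <- make_quants(ids, rounds, amounts)
  # marker = copy of NF amounts -> rho = 1
  out <- correlation_pipeline(nf, nf)
  expect_equal(out$result$rho, 1, tolerance = 1e-12)
  expect_equal(out$result$band, "high")
  expect_equal(out$result$n_spines, 60)
  # shuffled marker -> rho near 0
  withr::with_seed(62, shuf <- make_quants(ids, rounds, sample(amounts)))
  out0 <- correlation_pipeline(nf, shuf)
  expect_lt(abs(out0$result$rho), 3 / sqrt(60))
})

test_that("pooled Spearman is invariant to per-round affine corruption", {
  withr::with_seed(63, {
    n <- 90
    ids <- sprintf("s%03d", 1:n)
    rounds <- rep(c("r1", "r2", "r3"), each = 30)
    p <- sample_amount_pairs(n, list(nf = c(log(400), 0.6),
                                     marker = c(log(300), 0.5)), 0.5)
  })
  nf <- make_quants(ids, rounds, p$nf_amount)
  mk <- make_quants(ids, rounds, p$marker_amount)
  base <- correlation_pipeline(nf, mk)
  gains <- c(r1 = 0.6, r2 = 1.7, r3 = 3.1)
  offs <- c(r1 = 10, r2 = -2, r3 = 0)
  nf2 <- make_quants(ids, rounds, gains[rounds] * p$nf_amount + offs[rounds])
  mk2 <- make_quants(ids, rounds, gains[rounds] * p$marker_amount)
  corrupted <- correlation_pipeline(nf2, mk2)
  expect_equal(corrupted$result$rho, base$result$rho, tolerance = 1e-12)
})

test_that("excluded spines are removed before correlation", {
  ids <- sprintf("s%02d", 1:10)
  rounds <- rep("r1", 10)
  nf <- make_quants(ids, rounds, 1:10)
  mk <- make_quants(ids, rounds, c(1:9, 1000), excluded = c(rep(FALSE, 9), TRUE))
  out <- correlation_pipeline(nf, mk)
  expect_equal(out$result$n_spines, 9)
  expect_equal(out$result$rho, 1)
  out2 <- correlation_pipeline(nf, make_quants(ids, rounds, c(1:9, 1000)),
                               exclusions = "s10")
  expect_equal(out2$result$n_spines, 9)
  expect_error(correlation_pipeline(nf[1:2, ], mk[1:2, ]), "fewer than 3")
})

test_that("report_results writes tables, figures, and a no-data marker", {
  dir <- withr::local_tempdir()
  quants <- tibble::tibble(roi_id = sprintf("s%02d", 1:20),
                           area_um2 = seq(0.01, 0.4, length.out = 20),
                           excluded = rep(c(FALSE, TRUE), c(18, 2)))
  cor_res <- tibble::tibble(isoform = "NFL", marker = "homer", rho = 0.49,
                            p_value = 1e-10, n_spines = 18, band = "low")
  scatter <- tibble::tibble(spine_id = quants$roi_id[1:18],
                            round_id = "r1", z_nf = rnorm(18),
                            z_marker = rnorm(18))
  files <- report_results(dir, quants = quants, correlations = cor_res,
                          scatter = scatter)
  expect_true(file.exists(file.path(dir, "correlation_results.csv")))
  expect_true(file.exists(file.path(dir, "area_ecdf.png")))
  # plotted values equal table values
  tab <- utils::read.csv(file.path(dir, "scatter_data.csv"))
  expect_equal(tab$z_nf, scatter$z_nf)
  occ <- utils::read.csv(file.path(dir, "occupancy.csv"))
  expect_equal(occ$fraction, fraction_above_area(quants)$fraction)
  # empty report
  dir2 <- withr::local_tempdir()
  report_results(dir2)
  expect_true(file.exists(file.path(dir2, "no_data.txt")))
})

test_that("the end-to-end pipeline tracks simulator ground truth", {
  res <- run_spine_pipeline(small_scene_config(seed = 71, n_spines = 40))
  sc <- res$scene
  expect_equal(nrow(res$quants_nf), 40)
  # crossing flags largely agree with geometric truth
  expect_gte(mean(res$flags == sc$spines$crossed_by_axon), 0.9)
  # recovered correlation is in the neighbourhood of the generative one
  expect_lt(abs(res$correlation$result$rho - sc$rho_spearman_true), 0.35)
  # measured NF amounts rank-correlate with truth within rounds
  keep <- !res$flags
  for (r in unique(sc$spines$round_id[keep])) {
    i <- keep & sc$spines$round_id == r
    if (sum(i) < 5) next
    expect_gt(cor(sc$spines$true_nf_amount[i], res$quants_nf$amount[i],
                  method = "spearman"), 0.6)
  }
})

test_that("axon/spine intensity enrichment is recovered from rendered scenes", {
  ratios <- vapply(1:3, function(s) {
    cfg <- small_scene_config(seed = 100 + s, n_spines = 20)
    sc <- build_scene(cfg)
    ch <- render_channels(sc)
    nf <- offset_min_to_zero(ch$channels$nf)
    shape <- dim(nf$pixels)
    rois <- as_roi_set(sc)
    spine_means <- unlist(lapply(rois$rois, function(r) {
      if (r$label != "spine") return(NULL)
      m <- rasterize_roi(r$polygon, shape)$pixels
      mean_intensity_nonzero(nf, m)
    }))
    axon_means <- unlist(lapply(rois$rois, function(r) {
      if (r$label != "axon") return(NULL)
      m <- rasterize_roi(r$polygon, shape)$pixels
      if (!any(m)) return(NULL)
      mean_intensity_nonzero(nf, m)
    }))
    axon_spine_ratio(axon_means, spine_means)
  }, numeric(1))
  # axons are rendered brighter than spine puncta backgrounds on average
  expect_true(all(ratios > 1))
})
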