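test_that("background subtraction yields bright cells on a near-zero floor", {
  cfg <- mm_config()
  expect_true(all(mm_subtract_background(matrix(0.6, 40, 20), cfg = cfg) == 0))

  # dark rod on bright background -> bright rod, background within noise of 0
  set.seed(20)
  img <- matrix(0.75 + rnorm(150 * 20, 0, 0.01), 150, 20)
  rod <- draw_rod(150, 20, 40, 10, 25, 7) > 0
  img[rod] <- 0.35
  out <- mm_subtract_background(img, cfg = cfg)
  expect_gt(mean(out[rod]), 0.3)
  expect_lt(mean(abs(out[!rod])), 0.03)

  # a linear illumination gradient barely perturbs the result
  ramp <- matrix(seq(0, 0.08, length.out = 20), 150, 20, byrow = TRUE)
  out2 <- mm_subtract_background(img + ramp, cfg = cfg)
  amp <- mean(out[rod])
  expect_lt(mean(abs(out2[rod] - out[rod])), 0.05 * amp)
})

test_that("scale-space LoG peaks at blob centres across sizes", {
  expect_equal(max(abs(mm_scale_space_filter(matrix(0.3, 30, 30)))), 0)

  # Gaussian blob: response maximal at the centre
  g <- function(nr, nc, r0, c0, s0) {
    rr <- matrix(seq_len(nr), nr, nc); cc <- matrix(seq_len(nc), nr, nc, TRUE)
    exp(-((rr - r0)^2 + (cc - c0)^2) / (2 * s0^2))
  }
  img <- g(41, 41, 21, 21, 2.5)
  resp <- mm_scale_space_filter(img, scales = c(1.5, 2, 2.5, 3, 3.5))
  expect_identical(which.max(resp), which(matrix(seq_len(41 * 41), 41) == 21 + 20 * 41))

  # two blobs of different sizes are both local maxima of the projection
  img2 <- g(41, 81, 21, 20, 2) + g(41, 81, 21, 60, 3.5)
  resp2 <- mm_scale_space_filter(img2, scales = c(1.5, 2, 2.5, 3, 3.5))
  expect_gt(resp2[21, 20], max(resp2[21, 30:50]))
  expect_gt(resp2[21, 60], max(resp2[21, 30:50]))
})

test_that("initial segmentation finds separated rods and rejects specks", {
  cfg <- mm_config()
  set.seed(30)
  img <- matrix(0.02 * abs(rnorm(160 * 24)), 160, 24)
  truth <- list()
  for (i in 1:3) {
    r0 <- 25 + (i - 1) * 45
    img <- draw_rod(160, 24, r0, 12, 26, 7, value = 0.4, base = img)
    truth[[i]] <- draw_rod(160, 24, r0, 12, 26, 7) > 0
  }
  resp <- mm_scale_space_filter(img, cfg$log_scales)
  lab <- mm_segment_initial(resp, mm_threshold_li(resp), cfg)
  expect_equal(max(lab), 3)
  for (i in 1:3) {
    hit <- lab[truth[[i]]]
    expect_gte(mean(hit > 0), 0.5) # each rod recovered with >= 50% overlap
    expect_equal(length(unique(hit[hit > 0])), 1)
  }

  # one rod plus a 2-px speck: the speck is size-filtered away
  img3 <- draw_rod(80, 24, 30, 12, 26, 7, value = 0.4,
                   base = matrix(0, 80, 24))
  img3[60, 11:12] <- 0.4
  resp3 <- mm_scale_space_filter(img3, cfg$log_scales)
  lab3 <- mm_segment_initial(resp3, mm_threshold_li(resp3), cfg)
  expect_equal(max(lab3), 1)
  expect_equal(sum(lab3[55:65, ] > 0), 0)
})

test_that("an empty channel produces no detections at the frame threshold", {
  s <- mm_generate_series(mm_fixture_spec(
    n_frames = 1, seed = 13, n_cells_per_channel = c(2, 2, 0, 2, 2, 2, 2, 2)))
  cs <- mm_detect_channels(s$frames[[1]]$primary, "brightfield")
  bs <- mm_detect_bacteria(s$frames[[1]], cs)
  expect_equal(sum(bs$bacteria$channel_id == 3), 0)
  expect_gt(nrow(bs$bacteria), 0)
})

test_that("splitting requires both a constriction and a dim neck", {
  cfg <- mm_config()
  # two abutting rods with a narrow dim bridge
  neck <- draw_rod(90, 24, 30, 12, 28, 8, value = 0.4,
                   base = matrix(0, 90, 24))
  neck <- draw_rod(90, 24, 60, 12, 28, 8, value = 0.4, base = neck)
  neck[43:47, 11:13] <- 0.15 # dim 3-px-wide bridge joins them
  lab <- label_components(neck > 0)
  expect_equal(max(lab), 1) # genuinely one region before splitting
  out <- mm_split_adjacent(lab, neck, cfg = cfg)
  expect_equal(max(out), 2)
  # pixel conservation: children partition the parent exactly
  expect_identical(out > 0, lab > 0)

  # uniform rod: unchanged
  rod <- draw_rod(90, 24, 45, 12, 50, 8, value = 0.4,
                  base = matrix(0, 90, 24))
  lab2 <- label_components(rod > 0)
  expect_equal(max(mm_split_adjacent(lab2, rod, cfg = cfg)), 1)

  # dim point without constriction: both criteria required, so unchanged
  dim_rod <- rod
  dim_rod[44:46, 8:16][dim_rod[44:46, 8:16] > 0] <- 0.15
  expect_equal(max(mm_split_adjacent(lab2, dim_rod, cfg = cfg)), 1)
})

test_that("full-frame detection is accurate, in-channel, and deterministic", {
  s <- cached_series()
  res <- cached_result()
  bs <- res$bacteria_sets[[1]]
  tl <- s$truth$bacteria_labels[[1]]
  ids <- setdiff(unique(as.vector(tl)), 0)
  cov <- vapply(ids, function(id) mean(bs$labels[tl == id] > 0), numeric(1))
  expect_gte(mean(cov >= 0.5), 0.9) # >= 90% of cells detected

  # all detections fall inside channel masks
  cs <- res$channel_sets[[1]]
  expect_true(all(cs$labels[bs$labels > 0] > 0))

  # rerun on the identical frame: bit-identical label images
  bs2 <- mm_detect_bacteria(s$frames[[1]], cs)
  expect_identical(bs2$labels, bs$labels)
  expect_equal(bs2$bacteria, bs$bacteria)
})

test_that("adding an isolated bacterium never removes existing detections", {
  cfg <- mm_config()
  set.seed(77)
  base <- matrix(0.02 * abs(rnorm(160 * 24)), 160, 24)
  base <- draw_rod(160, 24, 30, 12, 26, 7, value = 0.4, base = base)
  base <- draw_rod(160, 24, 75, 12, 24, 7, value = 0.4, base = base)
  seg <- function(img) {
    resp <- mm_scale_space_filter(img, cfg$log_scales)
    mm_segment_initial(resp, mm_threshold_li(resp), cfg)
  }
  lab1 <- seg(base)
  with_extra <- draw_rod(160, 24, 125, 12, 25, 7, value = 0.4, base = base)
  lab2 <- seg(with_extra)
  expect_equal(max(lab2), max(lab1) + 1)
  for (id in seq_len(max(lab1))) {
    sel <- lab1 == id
    expect_gte(mean(lab2[sel] > 0), 0.9)
  }
})
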