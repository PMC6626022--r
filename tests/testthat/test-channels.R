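test_that("Li threshold agrees with exhaustive minimum-cross-entropy search", {
  set.seed(101)
  for (i in 1:20) {
    n <- 400
    x <- c(round(rnorm(n * 0.7, 60, 12)), round(rnorm(n * 0.3, 190, 15)))
    x <- pmin(pmax(x, 0), 255)
    img <- matrix(x, 20, 40)
    t_impl <- mm_threshold_li(img)
    expect_identical(img > t_impl, oracle_li_mask(img))
  }
})

test_that("Li threshold separates a bimodal image between its modes", {
  img <- matrix(c(rep(10, 60), rep(200, 40)), 10, 10)
  t <- mm_threshold_li(img)
  expect_gt(t, 10)
  expect_lt(t, 200)
  # one bright pixel lands in the mask
  img2 <- matrix(5, 9, 9); img2[5, 5] <- 250
  expect_true((img2 > mm_threshold_li(img2))[5, 5])
  expect_equal(sum(img2 > mm_threshold_li(img2)), 1)
  expect_error(mm_threshold_li(matrix(3, 5, 5)), "constant")
})

test_that("Li decision is invariant under affine intensity rescaling", {
  set.seed(55)
  for (i in 1:20) {
    img <- matrix(rnorm(300, 50, 25), 15, 20)
    base <- img > mm_threshold_li(img)
    a <- runif(1, 0.05, 20); b <- runif(1, -100, 100)
    scaled <- a * img + b
    expect_identical(scaled > mm_threshold_li(scaled), base)
  }
})

test_that("ridge filters highlight the expected structures", {
  flat <- matrix(0.5, 40, 40)
  expect_lt(max(mm_ridge_filter(flat, "brightfield")), 1e-6)
  expect_lt(max(mm_ridge_filter(flat, "phase")), 1e-6)

  # dark 3-px line on bright background: Frangi peaks on the line centre
  line <- matrix(0.9, 41, 41)
  line[, 20:22] <- 0.2
  fr <- mm_ridge_filter(line, "brightfield")
  peak_cols <- arrayInd(which.max(fr[10:30, ]), dim(fr[10:30, ]))[, 2]
  expect_true(all(abs(peak_cols - 21) <= 1))

  # step edge: Sobel magnitude is maximal on the edge
  step <- matrix(0.2, 40, 40)
  step[, 21:40] <- 0.8
  sb <- mm_ridge_filter(step, "phase")
  expect_true(all(abs(arrayInd(which.max(sb), dim(sb))[, 2] - 20.5) <= 1))
})

test_that("interiors are recovered from outlines, gaps closed, specks dropped", {
  cfg <- mm_config(channel_area_range = c(100, 50000))
  mask <- matrix(FALSE, 220, 60)
  mask[31:190, 21:22] <- TRUE; mask[31:190, 39:40] <- TRUE
  mask[31:32, 21:40] <- TRUE; mask[189:190, 21:40] <- TRUE
  interiors <- mm_extract_channel_regions(mask, cfg)
  expect_equal(max(interiors), 1)
  expect_true(all(interiors[80:100, 28:34] == 1)) # interior filled

  # a 2-px gap in the outline is closed by the dilation
  gap <- mask
  gap[100:101, 21:22] <- FALSE
  interiors2 <- mm_extract_channel_regions(gap, cfg)
  expect_equal(max(interiors2), 1)
  expect_true(all(interiors2[80:100, 28:34] == 1))

  # a 5-px speck falls below the component area filter
  speck <- mask
  speck[10, 50:54] <- TRUE
  interiors3 <- mm_extract_channel_regions(speck, cfg)
  expect_equal(max(interiors3), 1)
})

test_that("channel vectors are filtered by length under the scale factor", {
  make_interior <- function(len) {
    m <- matrix(FALSE, len + 40, 40)
    m[21:(20 + len), 16:25] <- TRUE
    label_components(m)
  }
  fit_len <- function(len, cfg) nrow(mm_fit_channel_vectors(make_interior(len),
                                                            cfg)$channels)
  cfg1 <- mm_config()
  expect_equal(fit_len(250, cfg1), 1) # inside 100-400
  expect_equal(fit_len(50, cfg1), 0)  # below range
  cfg05 <- mm_config(scale_factor = 0.5)
  expect_equal(fit_len(150, cfg05), 1) # bounds scale to 50-200
  expect_equal(fit_len(220, cfg05), 0)
})

test_that("fewer than three detected channels rejects the frame", {
  fit <- list(channels = data.frame(centroid_r = c(1, 2), centroid_c = c(1, 50),
                                    axis_r = c(100, 100), axis_c = c(0, 0),
                                    length = c(100, 100), width = c(10, 10),
                                    id = 1:2),
              labels = matrix(0L, 10, 10))
  expect_error(mm_interpolate_channels(fit, c(10, 10)),
               class = "mm_frame_rejected")
})

test_that("a missing channel is interpolated at the spacing grid", {
  s <- mm_generate_series(mm_fixture_spec(n_frames = 1, seed = 3))
  img <- s$frames[[1]]$primary
  tl <- s$truth$channel_labels[[1]]
  # erase channel 4 by painting background over it
  m4 <- which(tl == 4, arr.ind = TRUE)
  rr <- range(m4[, 1]); cc <- range(m4[, 2])
  img[(rr[1] - 8):(rr[2] + 8), (cc[1] - 8):(cc[2] + 8)] <- 0.75
  cs <- mm_detect_channels(img, "brightfield")
  expect_equal(nrow(cs$channels), 8)
  expect_identical(which(cs$channels$interpolated), 4L)
  # stamped centroid sits on the true channel 4 column
  true_col <- mean(which(tl == 4, arr.ind = TRUE)[, 2])
  expect_lt(abs(cs$channels$centroid_c[4] - true_col), 3)
})

test_that("constructed centroid gap of 2x spacing gets one stamped channel", {
  s <- mm_generate_series(mm_fixture_spec(n_frames = 1, seed = 9,
                                          n_cells_per_channel = 0))
  img <- s$frames[[1]]$primary
  tl <- s$truth$channel_labels[[1]]
  for (k in c(2, 6)) { # erase two non-adjacent channels
    px <- which(tl == k, arr.ind = TRUE)
    img[(min(px[, 1]) - 8):(max(px[, 1]) + 8),
        (min(px[, 2]) - 8):(max(px[, 2]) + 8)] <- 0.75
  }
  cs <- mm_detect_channels(img, "brightfield")
  expect_equal(nrow(cs$channels), 8)
  expect_equal(sum(cs$channels$interpolated), 2)
  expect_identical(which(cs$channels$interpolated), c(2L, 6L))
})

test_that("full fixture frames detect all channels in left-to-right order", {
  for (seed in c(3, 7)) {
    s <- mm_generate_series(mm_fixture_spec(n_frames = 1, seed = seed))
    cs <- mm_detect_channels(s$frames[[1]]$primary, "brightfield")
    expect_equal(nrow(cs$channels), 8)
    expect_identical(cs$channels$id, 1:8)
    expect_true(all(diff(cs$channels$centroid_c) > 0))
    # spacing recovered within 1 px of the true pitch
    expect_lt(abs(cs$spacing_px - 40), 1)
    # labels are disjoint by construction: ids are a permutation of 1..n
    expect_setequal(setdiff(unique(as.vector(cs$labels)), 0L), 1:8)
    # complete set: no interpolation needed, output matches input
    expect_false(any(cs$channels$interpolated))
  }
})

test_that("a tilted device is detected without tilt correction", {
  s <- mm_generate_series(mm_fixture_spec(n_frames = 1, seed = 3,
                                          device_angle = 10))
  cs <- mm_detect_channels(s$frames[[1]]$primary, "brightfield")
  expect_equal(nrow(cs$channels), 8)
  expect_lt(abs(cs$spacing_px - 40), 1)
  # axis direction reflects the tilt (farthest-pair axes carry a few
  # degrees of diagonal bias on wide interiors)
  ang <- atan2(cs$channels$axis_c[1], cs$channels$axis_r[1]) * 180 / pi
  expect_lt(abs(abs(ang) - 10), 6)
})

test_that("phase-contrast rendering is detected through the Sobel path", {
  s <- mm_generate_series(mm_fixture_spec(n_frames = 1, seed = 4,
                                          modality = "phase"))
  cs <- mm_detect_channels(s$frames[[1]]$primary, "phase")
  expect_equal(nrow(cs$channels), 8)
})
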