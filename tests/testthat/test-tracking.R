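test_that("frame shift is recovered exactly on rigid translations", {
  s <- mm_generate_series(mm_fixture_spec(n_frames = 1, seed = 21,
                                          noise_sigma = 0))
  img <- s$frames[[1]]$primary
  sh0 <- mm_estimate_frame_shift(img, img)
  expect_equal(c(sh0$dy, sh0$dx), c(0, 0))
  expect_gt(sh0$peak_correlation, 0.999)

  # shift the scene by (0, -12): translate columns
  shifted <- img[, c(13:ncol(img), rep(ncol(img), 12))]
  shifted[, (ncol(img) - 11):ncol(img)] <- 0.75
  sh <- mm_estimate_frame_shift(img, shifted)
  expect_equal(c(sh$dy, sh$dx), c(0, -12))

  # two independent noise images: warning and (0, 0) fallback
  set.seed(1)
  n1 <- matrix(rnorm(10000), 100, 100)
  n2 <- matrix(rnorm(10000), 100, 100)
  expect_warning(shn <- mm_estimate_frame_shift(n1, n2), "below floor")
  expect_equal(c(shn$dy, shn$dx), c(0, 0))
})

test_that("channel matching is mutual nearest neighbour", {
  mk <- function(cols) data.frame(id = seq_along(cols), centroid_r = 50,
                                  centroid_c = cols)
  none <- list(dy = 0, dx = 0)
  m1 <- mm_track_channels(mk(c(10, 60, 110)), mk(c(10, 60, 110)), none)
  expect_equal(m1$matches$prev_id, m1$matches$curr_id)

  # prev {0, 100} vs curr {5, 98}
  m2 <- mm_track_channels(mk(c(0, 100)), mk(c(5, 98)), none)
  expect_equal(m2$matches, data.frame(prev_id = 1:2, curr_id = 1:2))

  # a deleted channel leaves its prev id unmatched, others unaffected
  m3 <- mm_track_channels(mk(c(10, 60, 110)), mk(c(10, 110)), none)
  expect_equal(nrow(m3$matches), 2)
  expect_identical(m3$unmatched_prev, 2L)
  expect_length(m3$unmatched_curr, 0)
})

test_that("hypothesis enumeration matches brute-force event strings", {
  for (np in 0:3) for (nc in 0:3) {
    impl <- mm_enumerate_hypotheses(np, nc, division_cap = 2L)
    orac <- oracle_hypotheses(np, nc, division_cap = 2L)
    expect_setequal(vapply(impl, hypothesis_key, character(1)),
                    vapply(orac, hypothesis_key, character(1)))
  }
  # 1 prev, 1 curr: exactly {no-change} and {lysis + 1 new}
  h11 <- mm_enumerate_hypotheses(1, 1)
  expect_setequal(vapply(h11, hypothesis_key, character(1)),
                  c("1|0", "0|1"))
  # 1 prev, 2 curr includes the single-division hypothesis
  h12 <- vapply(mm_enumerate_hypotheses(1, 2), hypothesis_key, character(1))
  expect_true("2|0" %in% h12)
  # 2 prev, 1 curr includes both single-lysis assignments
  h21 <- vapply(mm_enumerate_hypotheses(2, 1), hypothesis_key, character(1))
  expect_true(all(c("0,1|0", "1,0|0") %in% h21))
})

test_that("hypothesis scoring prefers the physically plausible event", {
  cfg <- mm_config()
  params <- list(p_no_change = cfg$p_no_change, p_division = cfg$p_division,
                 p_lysis = cfg$p_lysis, area_sigma = cfg$area_sigma,
                 centroid_sigma = 10, mean_bacterium_length = 20)
  score_all <- function(prev_pos, prev_area, curr_pos, curr_area) {
    hyps <- mm_enumerate_hypotheses(length(prev_pos), length(curr_pos))
    s <- vapply(hyps, mm_score_hypothesis, numeric(1), prev_pos, prev_area,
                curr_pos, curr_area, params)
    list(hyps = hyps, scores = s)
  }
  # identical frames: no-change scores strictly highest
  r <- score_all(c(10, 40), c(150, 160), c(10, 40), c(150, 160))
  keys <- vapply(r$hyps, hypothesis_key, character(1))
  expect_identical(keys[which.max(r$scores)], "1,1|0")
  expect_gt(max(r$scores), max(r$scores[keys != "1,1|0"]))

  # 200-px parent -> two adjacent 100-px children: division beats lysis+2 new
  r2 <- score_all(20, 200, c(12, 32), c(100, 100))
  keys2 <- vapply(r2$hyps, hypothesis_key, character(1))
  expect_gt(r2$scores[keys2 == "2|0"], r2$scores[keys2 == "0|2"])
  expect_identical(keys2[which.max(r2$scores)], "2|0")

  # all probabilities live in (0, 1]
  expect_true(all(r$scores > 0 & r$scores <= 1))
  expect_true(all(r2$scores > 0 & r2$scores <= 1))
})

test_that("a static series tracks as straight no-change chains", {
  s <- mm_generate_series(mm_fixture_spec(n_frames = 5, seed = 31,
                                          growth_rate = 0))
  res <- mm_analyze(s)
  nd <- res$graph$nodes
  expect_equal(sum(nd$event == "division"), 0)
  expect_equal(sum(nd$event == "new" & nd$frame > 1), 0)
  expect_equal(sum(!is.na(nd$fate)), 0)
  # every track spans all five frames with one stable global id
  spans <- table(nd$global_id)
  expect_true(all(spans == 5))
})

test_that("programmed division and lysis appear in the track graph", {
  res <- cached_result()
  s <- cached_series()
  nd <- res$graph$nodes
  # the division at frame 3 produces exactly two children of one parent
  kids <- nd[nd$event == "division", ]
  expect_equal(nrow(kids), 2)
  expect_equal(kids$frame, c(3L, 3L))
  expect_equal(length(unique(kids$parent_id)), 1)
  # no-change chains keep their id across the whole series
  te <- mm_tracking_efficiency(res, s$truth)
  expect_equal(te$efficiency, 100)
})

test_that("a lysing cell terminates with a lysis fate", {
  s <- mm_generate_series(mm_fixture_spec(
    n_frames = 4, seed = 17,
    lysis_schedule = data.frame(channel = 3, frame = 3, cell = 1)))
  res <- mm_analyze(s)
  nd <- res$graph$nodes
  lys <- nd[!is.na(nd$fate) & nd$fate == "lysis", ]
  expect_equal(nrow(lys), 1)
  expect_equal(lys$frame, 2L) # last seen at frame 2, gone at frame 3
  expect_equal(lys$channel_id, 3L)
})
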