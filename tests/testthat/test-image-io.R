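test_that("protocol filenames parse to area id and timestamp", {
  p <- mm_parse_filename("Area01_171016_123301.tiff")
  expect_identical(p$area_id, "Area01")
  expect_equal(p$timestamp,
               as.POSIXct("2017-10-16 12:33:01", tz = "UTC"))
  # underscores inside the prefix are part of the area id
  p2 <- mm_parse_filename("exp_2_Area01_171016_123301.tif")
  expect_identical(p2$area_id, "exp_2_Area01")
  # one-second ordering
  a <- mm_parse_filename("Area01_171016_123301.tiff")$timestamp
  b <- mm_parse_filename("Area01_171016_123302.tiff")$timestamp
  expect_equal(as.numeric(b - a, units = "secs"), 1)
})

test_that("malformed filenames are rejected with the offending name", {
  expect_error(mm_parse_filename("snapshot.tiff"), "snapshot")
  expect_error(mm_parse_filename("Area01_171316_123301.tiff"), "malformed")
  expect_error(mm_parse_filename("Area01_171016_253301.tiff"), "malformed")
})

test_that("frames load with the declared plane layout", {
  d <- withr::local_tempdir()
  img <- matrix(runif(200), 10, 20)
  f1 <- file.path(d, "Area01_171016_120000.tiff")
  tiff::writeTIFF(img, f1, bits.per.sample = 16L)
  fr <- mm_load_frame(f1, n_fluo = 0)
  expect_length(fr$fluorescence, 0)
  expect_identical(dim(fr$primary), c(10L, 20L))
  expect_identical(fr$area_id, "Area01")

  f2 <- file.path(d, "Area01_171016_130000.tiff")
  tiff::writeTIFF(list(img, img / 2), f2, bits.per.sample = 16L)
  fr2 <- mm_load_frame(f2, n_fluo = 1)
  expect_length(fr2$fluorescence, 1)
  expect_equal(dim(fr2$fluorescence[[1]]), dim(fr2$primary))
  # declared plane count must match the file
  expect_error(mm_load_frame(f2, n_fluo = 0), "expected 1 plane")
  expect_error(mm_load_frame(f1, n_fluo = 1), "expected 2 plane")
})

test_that("16-bit TIFF round trip is lossless", {
  d <- withr::local_tempdir()
  vals <- matrix(sample(0:65535, 150) / 65535, 10, 15)
  f <- file.path(d, "Area01_171016_120000.tiff")
  tiff::writeTIFF(vals, f, bits.per.sample = 16L)
  fr <- mm_load_frame(f, 0)
  expect_equal(fr$primary, vals, tolerance = 1e-12)
})

test_that("batch indexing groups by area and orders chronologically", {
  d <- withr::local_tempdir()
  img <- matrix(runif(100), 10, 10)
  names <- c("Area02_171016_120000.tiff", "Area01_171016_140000.tiff",
             "Area01_171016_120000.tiff", "Area01_171016_130000.tiff",
             "notes.txt", "bad_name.tiff")
  for (n in names) {
    if (grepl("tiff$", n)) tiff::writeTIFF(img, file.path(d, n))
    else writeLines("x", file.path(d, n))
  }
  idx <- mm_index_batch(d)
  expect_setequal(names(idx), c("Area01", "Area02"))
  expect_equal(nrow(idx$Area01), 3)
  expect_true(all(diff(idx$Area01$timestamp) > 0))
  expect_equal(nrow(idx$Area02), 1)
})

test_that("measurement CSV writes the schema and round-trips", {
  d <- withr::local_tempdir()
  f <- file.path(d, "out.csv")
  empty <- data.frame()
  mm_write_measurements(empty, f, n_fluo = 1)
  hdr <- readLines(f, n = 1)
  expect_match(hdr, "area_id.*bacterium_id.*parent_id.*event.*length_px")
  expect_match(hdr, "fluo1_mean.*fluo1_background")
  expect_equal(nrow(mm_read_measurements(f)), 0)

  rec <- data.frame(area_id = "Area01", timestamp = "2017-10-16 12:00:00",
                    frame_index = 1L, channel_id = 2L, bacterium_id = 7L,
                    parent_id = NA_integer_, event = "new",
                    length_px = 21.5, width_px = 7.25, area_px = 150,
                    fluo1_mean = 88.125, fluo1_background = 11.5)
  mm_write_measurements(rec, f)
  back <- mm_read_measurements(f)
  expect_equal(nrow(back), 1)
  expect_equal(back$length_px, 21.5)
  expect_equal(back$fluo1_mean, 88.125)
  expect_identical(back$event, "new")
})

test_that("a tracked division yields child rows sharing the parent id", {
  d <- withr::local_tempdir()
  res <- cached_result()
  f <- file.path(d, "series.csv")
  mm_export_csv(res, f)
  back <- mm_read_measurements(f)
  kids <- back[back$event == "division", ]
  expect_gte(nrow(kids), 2)
  expect_true(any(table(kids$parent_id, kids$frame_index) == 2))
})
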