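make_stream <- function(values) {
  frame_stream(lapply(values, function(v) matrix(v, 8, 10)))
}

test_that("background model averages the surrounding frames", {
  # constant stream
  fs <- make_stream(rep(200, 60))
  bg <- build_background(fs, 30, window = 50)
  expect_true(all(bg$mean_image == 200))
  expect_equal(length(bg$frames_used), 50L)
  expect_false(30 %in% bg$frames_used)
  # window holding 25 frames of 100 and 25 of 200: arithmetic mean 150
  fs2 <- make_stream(c(rep(100, 25), 170, rep(200, 25)))
  bg2 <- build_background(fs2, 26, window = 50)
  expect_true(all(bg2$mean_image == 150))
  expect_false(26 %in% bg2$frames_used)
  # stream shorter than window errors with advice
  expect_error(build_background(make_stream(rep(1, 10)), 5, window = 50),
               "smaller")
})

test_that("background window truncates by shifting at stream ends", {
  fs <- make_stream(1:60)
  for (i in c(1, 2, 30, 59, 60)) {
    bg <- build_background(fs, i, window = 50)
    expect_equal(length(bg$frames_used), 50L)
    expect_false(i %in% bg$frames_used)
    expect_true(all(bg$frames_used >= 1 & bg$frames_used <= 60))
    # contiguous block around the target
    expect_lte(diff(range(bg$frames_used)), 51L)
  }
})

test_that("foreground is the set of pixels deviating beyond the threshold", {
  bgm <- matrix(180, 60, 80)
  expect_false(any(foreground_mask(bgm, bgm, 25)))
  disc <- disc_mask(c(60, 80), 30, 40, 10)
  frame <- bgm - 80 * disc
  expect_identical(foreground_mask(frame, bgm, 25), disc)
  # unreachable threshold on 8-bit data
  expect_false(any(foreground_mask(frame, bgm, 255)))
  expect_error(foreground_mask(matrix(0, 2, 2), bgm, 25), "shape")
  expect_error(foreground_mask(bgm, bgm, 0), "positive")
})

test_that("blob detection respects connectivity and partitions the mask", {
  m <- matrix(FALSE, 40, 40)
  m[3:12, 3:12] <- TRUE
  m[25:34, 25:34] <- TRUE
  b <- detect_blobs(m, 8)
  expect_equal(nrow(b), 2L)
  expect_equal(sort(b$area_px), c(100L, 100L))
  expect_equal(sum(b$area_px), sum(m))
  expect_equal(nrow(detect_blobs(matrix(FALSE, 5, 5))), 0L)
  # diagonal pair: one blob under 8-connectivity, two under 4
  d <- matrix(FALSE, 5, 5); d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_equal(nrow(detect_blobs(d, 8)), 1L)
  expect_equal(nrow(detect_blobs(d, 4)), 2L)
})

test_that("blob areas always partition the foreground", {
  set.seed(5)
  for (i in 1:10) {
    m <- matrix(runif(30 * 30) < 0.35, 30, 30)
    for (conn in c(4, 8)) {
      b <- detect_blobs(m, conn)
      expect_equal(sum(b$area_px), sum(m))
    }
  }
})

test_that("blob filtering keeps large blobs and preserves order", {
  m <- matrix(FALSE, 100, 120)
  m[2:6, 2:11] <- TRUE        # 50 px
  m[30:79, 21:120] <- TRUE    # 5000 px
  b <- detect_blobs(m)
  expect_equal(nrow(filter_blobs(b, min_area = 1000)), 1L)
  expect_equal(filter_blobs(b, min_area = 1000)$area_px, 5000L)
  expect_identical(filter_blobs(b, 0, 0), b)
  expect_equal(nrow(filter_blobs(b, min_area = 0, min_bbox_side = 20)), 1L)
})

test_that("a synthetic egg-sized blob survives the default area filter", {
  # disc of diameter 1.3 mm at 0.0036 mm/px: area ~ pi * 180.5^2 ~ 102000 px
  r_px <- 1.3 / 2 / 0.0036
  m <- disc_mask(c(400, 400), 200, 200, r_px)
  b <- filter_blobs(detect_blobs(m), min_area = 100000)
  expect_equal(nrow(b), 1L)
  expect_equal(b$area_px / (pi * r_px^2), 1, tolerance = 0.01)
})

test_that("candidate selection finds exactly the injected frames", {
  st <- render_stream(n_frames = 60, injection_frames = c(7, 21, 33, 48, 55),
                      n_distractors = 6, image_shape = c(70, 90),
                      scale = 0.01, object_diameter_mm = 0.55, seed = 42)
  cfg <- selection_config(window = 20, scale = px_scale(0.01))
  cand <- select_candidates(st$stream, cfg)
  expect_identical(which(cand$manifest$selected), c(7L, 21L, 33L, 48L, 55L))
  expect_identical(nrow(cand$manifest), 60L)
  # selected implies surviving blobs
  expect_true(all(cand$manifest$n_blobs[cand$manifest$selected] >= 1))
})

test_that("selection is invariant to a global additive intensity offset", {
  st <- render_stream(n_frames = 40, injection_frames = c(10, 30),
                      image_shape = c(40, 50), scale = 0.01,
                      object_diameter_mm = 0.3, seed = 3)
  cfg <- selection_config(window = 16, min_area_mm2 = 0.05,
                          scale = px_scale(0.01))
  base <- select_candidates(st$stream, cfg)
  shifted <- frame_stream(st$stream$pixels + 17)
  expect_identical(select_candidates(shifted, cfg)$manifest, base$manifest)
})

test_that("an object present in every frame is absorbed by the background", {
  disc <- disc_mask(c(40, 50), 20, 25, 8)
  fs <- frame_stream(lapply(1:30, function(i) matrix(220, 40, 50) - 80 * disc))
  cand <- select_candidates(fs, selection_config(window = 16,
                                                 min_area_mm2 = 0.01,
                                                 scale = px_scale(0.01)))
  expect_false(any(cand$manifest$selected))
})

test_that("flat noiseless streams yield zero selections", {
  fs <- make_stream(rep(150, 40))
  cand <- select_candidates(fs, selection_config(window = 20,
                                                 scale = px_scale(0.01)))
  expect_false(any(cand$manifest$selected))
})

test_that("fast path matches the explicit-loop oracle on a miniature stream", {
  st <- render_stream(n_frames = 30, injection_frames = c(5, 17, 26),
                      n_distractors = 3, image_shape = c(30, 40),
                      scale = 0.01, object_diameter_mm = 0.2, seed = 9)
  w <- 12; thr <- 25
  for (i in c(1, 5, 14, 26, 30)) {
    bg <- build_background(st$stream, i, w)
    nb <- naive_background(st$stream, i, w)
    expect_equal(bg$mean_image, nb, tolerance = 1e-10)
    fg <- foreground_mask(get_frame(st$stream, i), bg, thr)
    expect_identical(fg, naive_foreground(get_frame(st$stream, i), nb, thr))
    for (conn in c(4, 8)) {
      lab <- naive_label(fg, conn)
      b <- detect_blobs(fg, conn)
      expect_equal(nrow(b), max(lab))
    }
  }
})

test_that("the selection manifest CSV records one row per frame", {
  st <- render_stream(n_frames = 30, injection_frames = 15,
                      image_shape = c(30, 40), scale = 0.01,
                      object_diameter_mm = 0.2, seed = 2)
  cand <- select_candidates(st$stream, selection_config(window = 12,
                                                        min_area_mm2 = 0.02,
                                                        scale = px_scale(0.01)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_selection_manifest(cand, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 30L)
  expect_equal(names(back), c("frame_index", "n_blobs", "max_blob_area_px",
                              "selected"))
  expect_equal(which(back$selected), 15L)
})
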