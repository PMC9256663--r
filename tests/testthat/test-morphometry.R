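test_that("centerline length of a rectangle matches its long side", {
  m <- rect_mask(c(120, 480), 40, 79, 40, 439)   # 400 x 40 px
  cl <- extract_centerline(m)
  expect_equal(cl$arc_length_px, 400, tolerance = 0.02)
  expect_true(all(m[round(cl$points)]))
})

test_that("centerline follows a curved tube to its analytic arc length", {
  # semicircular tube, centerline radius 200 px, half-width 15 px
  m <- arc_tube_mask(c(260, 460), c(240, 230), 200, 15)
  cl <- extract_centerline(m)
  expect_equal(cl$arc_length_px, pi * 200, tolerance = 0.03)
})

test_that("a disc degenerates to a flagged diameter-length centerline", {
  m <- disc_mask(c(120, 120), 60, 60, 40)
  cl <- extract_centerline(m)
  expect_true("low_elongation" %in% cl$flags)
  expect_equal(cl$arc_length_px, 80, tolerance = 0.06)
  expect_error(extract_centerline(matrix(FALSE, 5, 5)), "empty")
  two <- matrix(FALSE, 20, 20); two[3, 3] <- TRUE; two[15, 15] <- TRUE
  expect_error(extract_centerline(two), "disconnected")
})

test_that("standard length converts centerline arc to mm", {
  cl <- structure(list(points = cbind(1, c(1, 1245)), arc_length_px = 1244,
                       flags = character()), class = "centerline")
  expect_equal(standard_length(cl, px_scale(0.0036)), 4.4784)
})

test_that("facing direction identifies the wider head end", {
  sc <- render_larva(larva_spec(), image_shape = c(400, 1400), seed = 5,
                     noise_sd = 0)
  body <- sc$regions[[1]]$mask
  cl <- extract_centerline(body)
  fd <- facing_direction(body, cl)
  expect_false(fd$ambiguous)
  truth_head <- sc$objects[[1]]$head_px
  expect_lt(sqrt(sum((fd$head - truth_head)^2)), 12)
  # mirrored image: heading mirrors exactly
  bodym <- body[, rev(seq_len(ncol(body)))]
  clm <- extract_centerline(bodym)
  fdm <- facing_direction(bodym, clm)
  expect_equal(fdm$heading[["dcol"]], -fd$heading[["dcol"]], tolerance = 0.05)
  expect_equal(fdm$heading[["drow"]], fd$heading[["drow"]], tolerance = 0.05)
})

test_that("head detection succeeds across poses and angles", {
  set.seed(91)
  angles <- runif(12, 0, 2 * pi)
  turns <- runif(12, 0, pi / 2)
  hits <- 0L
  for (i in seq_along(angles)) {
    sc <- render_larva(larva_spec(angle_rad = angles[i], turn_rad = turns[i]),
                       image_shape = c(1000, 1300), seed = 100 + i, noise_sd = 0)
    body <- sc$regions[[1]]$mask
    fd <- facing_direction(body, extract_centerline(body))
    truth_head <- sc$objects[[1]]$head_px
    truth_tail <- sc$objects[[1]]$tail_px
    d_head <- sqrt(sum((fd$head - truth_head)^2))
    d_tail <- sqrt(sum((fd$head - truth_tail)^2))
    hits <- hits + (d_head < d_tail)
  }
  expect_equal(hits, 12L)
})

test_that("a symmetric capsule yields an ambiguous heading", {
  m <- rect_mask(c(100, 400), 40, 60, 60, 340) |
    disc_mask(c(100, 400), 50, 60, 10) | disc_mask(c(100, 400), 50, 340, 10)
  cl <- extract_centerline(m)
  fd <- facing_direction(m, cl)
  expect_true(fd$ambiguous)
})

test_that("second-moment axes recover rasterized ellipse dimensions", {
  # oracle: the analytic axes used to rasterize
  m <- ellipse_mask(c(200, 200), 100, 100, 60, 30)
  ax <- measure_axes(m)
  expect_equal(ax$major_px, 120, tolerance = 1 / 120)
  expect_equal(ax$minor_px, 60, tolerance = 1 / 60)
  # disc: isotropic
  d <- disc_mask(c(160, 160), 80, 80, 50)
  axd <- measure_axes(d)
  expect_equal(axd$major_px, 100, tolerance = 0.01)
  expect_equal(axd$minor_px, 100, tolerance = 0.01)
  # rotation invariance of axes, equivariance of orientation
  th <- 37 * pi / 180
  mr <- ellipse_mask(c(260, 260), 130, 130, 60, 30, angle = th)
  axr <- measure_axes(mr)
  expect_equal(axr$major_px, 120, tolerance = 1 / 120)
  expect_equal(axr$minor_px, 60, tolerance = 1 / 60)
  expect_equal(axr$orientation_rad, th, tolerance = pi / 180)
  expect_error(measure_axes(matrix(FALSE, 4, 4)), "empty")
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_true(measure_axes(one)$degenerate)
})

test_that("axis sweep stays within one pixel across sizes and orientations", {
  set.seed(41)
  n <- 40
  ok <- 0L
  for (i in seq_len(n)) {
    a <- runif(1, 10, 200)               # semi-major: full axis 20-400 px
    b <- runif(1, 5, a)
    th <- runif(1, 0, pi)
    sh <- ceiling(2 * a) + 20
    m <- ellipse_mask(c(sh, sh), sh / 2, sh / 2, a, b, th)
    ax <- measure_axes(m)
    ok <- ok + (abs(ax$major_px - 2 * a) <= 1 && abs(ax$minor_px - 2 * b) <= 1)
  }
  expect_gte(ok / n, 0.99)
})

test_that("measurements are equivariant under exact pixel symmetries", {
  sc <- render_larva(larva_spec(turn_rad = 0.4 * pi),
                     image_shape = c(800, 1200), seed = 6, noise_sd = 0)
  body <- sc$regions[[1]]$mask
  cl <- extract_centerline(body)
  for (tf in list(function(m) t(m),                        # transpose (reflect)
                  function(m) m[nrow(m):1, ],              # vertical flip
                  function(m) m[, ncol(m):1])) {           # horizontal flip
    mt <- tf(body)
    clt <- extract_centerline(mt)
    expect_equal(clt$arc_length_px, cl$arc_length_px, tolerance = 0.01)
    expect_equal(sum(mt), sum(body))
  }
})

test_that("a full individual is measured within tolerance of generator truth", {
  sc <- render_larva(larva_spec(), image_shape = c(400, 1400), seed = 12,
                     noise_sd = 0)
  segs <- postprocess(sc$regions, dim(sc$image), "larva")
  rec <- measure_individual(segs[[1]], px_scale(0.0036), "larva")
  tr <- sc$objects[[1]]
  expect_true(rec$body_valid && rec$yolk_valid && rec$eyes_valid)
  expect_equal(rec$standard_length_mm, tr$sl_mm, tolerance = 0.02)
  expect_equal(rec$body_area_mm2, tr$area_mm2, tolerance = 0.03)
  expect_equal(rec$yolk_length_mm, tr$yolk_length_mm, tolerance = 0.03)
  expect_equal(rec$yolk_width_mm, tr$yolk_width_mm, tolerance = 0.03)
  expect_equal(rec$eye_diameter_mm, tr$eye_diameter_mm, tolerance = 0.03)
  # derived volumes agree with the models applied to the truth inputs
  expect_equal(rec$total_volume_mm3,
               larva_total_volume(rec$body_area_mm2, rec$standard_length_mm))
  expect_equal(rec$structural_volume_mm3,
               rec$total_volume_mm3 - rec$yolk_volume_mm3)
})

test_that("a bodiless segmentation reports organs with body_valid FALSE", {
  seg <- structure(list(
    body = NULL,
    eyes = list(region_of("eye", ellipse_mask(c(100, 100), 50, 50, 42, 40))),
    yolk = region_of("yolk", ellipse_mask(c(100, 100), 50, 50, 20, 10)),
    body_discarded_reason = "edge_contact", flags = character()),
    class = "fish_segmentation")
  rec <- measure_individual(seg, px_scale(0.0036), "larva")
  expect_false(rec$body_valid)
  expect_true(is.na(rec$standard_length_mm))
  expect_true(rec$yolk_valid)
  expect_false(is.na(rec$eye_diameter_mm))
})

test_that("egg mode measures shell axes, mean diameter and sphere volume", {
  r_px <- 1.36 / 2 / 0.0036
  m <- disc_mask(c(450, 450), 225, 225, r_px)
  seg <- structure(list(body = region_of("egg", m), eyes = list(), yolk = NULL,
                        body_discarded_reason = "none", flags = character()),
                   class = "fish_segmentation")
  rec <- measure_individual(seg, px_scale(0.0036), "egg")
  expect_true(rec$egg_valid)
  expect_equal(rec$egg_diameter_mm, 1.36, tolerance = 0.0036 / 1.36)
  expect_equal(rec$egg_radius_mm, rec$egg_diameter_mm / 2)
  expect_equal(rec$egg_volume_mm3, egg_volume(rec$egg_diameter_mm))
  expect_gt(rec$circularity, 0.99)
  # no larva fields in egg mode
  expect_false(any(grepl("^yolk_|^eye_|standard_length", names(rec))))
})
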