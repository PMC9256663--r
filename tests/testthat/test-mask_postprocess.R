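shape <- c(100, 120)

test_that("hole filling closes enclosed holes and is idempotent", {
  outer_d <- disc_mask(shape, 50, 60, 30)
  inner_d <- disc_mask(shape, 50, 60, 10)
  annulus <- region_of("yolk", outer_d & !inner_d)
  filled <- fill_holes(annulus)
  # oracle: pixel counts of the constructed shapes
  expect_equal(filled$area_px, annulus$area_px + sum(inner_d))
  expect_identical(filled$mask, outer_d)
  expect_identical(fill_holes(filled)$mask, filled$mask)
  # solid disc unchanged
  solid <- region_of("yolk", outer_d)
  expect_identical(fill_holes(solid)$mask, solid$mask)
  expect_gte(filled$area_px, annulus$area_px)
})

test_that("concavities open to the image border are not filled", {
  m <- matrix(FALSE, 20, 20)
  m[1:15, 5:15] <- TRUE
  m[1:8, 9:11] <- FALSE   # slot open to row-1 border
  filled <- fill_holes(m)
  expect_identical(filled, m)
})

test_that("edge-touching bodies are discarded while interior organs survive", {
  body <- rect_mask(shape, 1, 60, 20, 100)       # touches row 1
  eye <- disc_mask(shape, 40, 40, 5)
  yolk <- ellipse_mask(shape, 45, 70, 12, 6)
  res <- discard_edge_bodies(list(region_of("body", body), region_of("eye", eye),
                                  region_of("yolk", yolk)), shape)
  expect_length(res$kept, 2L)
  expect_true(res$body_discarded)
  expect_setequal(vapply(res$kept, function(r) r$feature_class, ""),
                  c("eye", "yolk"))
  expect_equal(res$discarded$reason, "edge_contact")
  # all-interior input is untouched
  interior <- list(region_of("body", disc_mask(shape, 50, 60, 20)))
  res2 <- discard_edge_bodies(interior, shape)
  expect_length(res2$kept, 1L)
  expect_false(res2$body_discarded)
  # an eye on the border is itself removed
  edge_eye <- matrix(FALSE, shape[1], shape[2]); edge_eye[1, 5:9] <- TRUE
  res3 <- discard_edge_bodies(list(region_of("eye", edge_eye)), shape)
  expect_length(res3$kept, 0L)
  expect_false(res3$body_discarded)
})

test_that("containment tolerates exactly the configured pixel slack", {
  body <- region_of("body", disc_mask(shape, 50, 60, 30))
  inside <- region_of("eye", disc_mask(shape, 50, 60, 8))
  expect_length(enforce_containment(body, list(inside)), 1L)
  disjoint <- region_of("yolk", disc_mask(shape, 10, 10, 5))
  expect_length(enforce_containment(body, list(disjoint)), 0L)
  # overhanging part: oracle = count of part pixels outside the body
  over <- region_of("eye", disc_mask(shape, 50, 87, 5))
  n_out <- sum(over$mask & !body$mask)
  expect_gt(n_out, 0)
  expect_length(enforce_containment(body, list(over), slack = n_out - 1), 0L)
  expect_length(enforce_containment(body, list(over), slack = n_out), 1L)
})

test_that("cardinality enforcement keeps top confidence with stated tie-breaks", {
  mk <- function(conf, r0, area_r) region_of("eye", disc_mask(shape, r0, 60, area_r), conf)
  eyes <- list(mk(0.9, 20, 4), mk(0.8, 50, 4), mk(0.4, 80, 4))
  kept <- enforce_cardinality(eyes, "eye")
  expect_equal(kept$n_excess, 1L)
  expect_setequal(vapply(kept$kept, function(r) r$confidence, 0), c(0.9, 0.8))
  # single body passes through
  one <- enforce_cardinality(list(region_of("body", disc_mask(shape, 50, 60, 10))), "body")
  expect_equal(one$n_excess, 0L)
  # equal confidence: larger area wins
  y1 <- region_of("yolk", rect_mask(shape, 10, 34, 10, 29), 0.5)   # 500 px
  y2 <- region_of("yolk", rect_mask(shape, 60, 74, 60, 79), 0.5)   # 300 px
  kept2 <- enforce_cardinality(list(y2, y1), "yolk")
  expect_equal(kept2$kept[[1]]$area_px, 500L)
  # equal confidence and area: upper-left centroid wins (deterministic)
  z1 <- region_of("yolk", rect_mask(shape, 10, 19, 10, 19), 0.5)
  z2 <- region_of("yolk", rect_mask(shape, 60, 69, 60, 69), 0.5)
  expect_equal(enforce_cardinality(list(z2, z1), "yolk")$kept[[1]]$bbox[["rmin"]], 10)
})

test_that("parts are associated with the body containing most of their pixels", {
  bodyA <- region_of("body", rect_mask(shape, 10, 45, 5, 115))
  bodyB <- region_of("body", rect_mask(shape, 55, 90, 5, 115))
  eA1 <- region_of("eye", disc_mask(shape, 20, 20, 4))
  eA2 <- region_of("eye", disc_mask(shape, 20, 40, 4))
  yA <- region_of("yolk", ellipse_mask(shape, 30, 70, 10, 5))
  eB1 <- region_of("eye", disc_mask(shape, 65, 20, 4))
  eB2 <- region_of("eye", disc_mask(shape, 65, 40, 4))
  yB <- region_of("yolk", ellipse_mask(shape, 75, 70, 10, 5))
  segs <- associate_parts(list(bodyA, bodyB), list(eA1, eA2, yA, eB1, eB2, yB))
  expect_length(segs, 2L)
  for (s in segs) {
    expect_length(s$eyes, 2L)
    expect_false(is.null(s$yolk))
    # containment verified by pixel arithmetic
    for (p in c(s$eyes, list(s$yolk)))
      expect_equal(sum(p$mask & !s$body$mask), 0L)
  }
  # a part outside every body is dropped when a body exists
  stray <- region_of("eye", disc_mask(shape, 97, 110, 2))
  segs2 <- associate_parts(list(region_of("body", rect_mask(shape, 10, 45, 5, 115))),
                           list(stray))
  expect_length(segs2, 1L)
  expect_length(segs2[[1]]$eyes, 0L)
  # bodiless grouping when no body exists, recording the edge-discard reason
  segs3 <- associate_parts(list(), list(eA1, yA), body_discarded = TRUE)
  expect_length(segs3, 1L)
  expect_null(segs3[[1]]$body)
  expect_equal(segs3[[1]]$body_discarded_reason, "edge_contact")
  segs4 <- associate_parts(list(), list(eA1), body_discarded = FALSE)
  expect_length(segs4, 1L)
  expect_equal(segs4[[1]]$body_discarded_reason, "none")
})

test_that("postprocess applies the full rule set and is idempotent", {
  body <- disc_mask(shape, 50, 60, 35) | rect_mask(shape, 40, 60, 20, 100)
  holey_yolk <- ellipse_mask(shape, 50, 80, 10, 6) &
    !disc_mask(shape, 50, 80, 3)                      # yolk with a hole
  eye1 <- disc_mask(shape, 45, 40, 4)
  eye2 <- disc_mask(shape, 55, 40, 4)
  regions <- list(region_of("body", body), region_of("yolk", holey_yolk),
                  region_of("eye", eye1), region_of("eye", eye2))
  segs <- postprocess(regions, shape, "larva")
  expect_length(segs, 1L)
  s <- segs[[1]]
  # the yolk hole was filled
  expect_equal(s$yolk$area_px, sum(ellipse_mask(shape, 50, 80, 10, 6)))
  expect_length(s$eyes, 2L)
  # idempotence: re-running on the surviving regions changes nothing
  again <- postprocess(ichmorph:::segmentation_regions(segs), shape, "larva")
  expect_length(again, 1L)
  expect_identical(again[[1]]$body$mask, s$body$mask)
  expect_identical(again[[1]]$yolk$mask, s$yolk$mask)
  expect_equal(length(again[[1]]$eyes), length(s$eyes))
  expect_length(postprocess(list(), shape, "larva"), 0L)
})

test_that("cardinality caps of one body, two eyes, one yolk always hold", {
  set.seed(8)
  body <- region_of("body", rect_mask(shape, 20, 80, 10, 110))
  parts <- list()
  for (i in 1:5) parts <- c(parts, list(
    region_of("eye", disc_mask(shape, 20 + 12 * i, 30, 3), runif(1))))
  for (i in 1:3) parts <- c(parts, list(
    region_of("yolk", disc_mask(shape, 20 + 18 * i, 80, 4), runif(1))))
  segs <- postprocess(c(list(body), parts), shape, "larva")
  expect_length(segs, 1L)
  expect_lte(length(segs[[1]]$eyes), 2L)
  expect_true(is.null(segs[[1]]$yolk) || inherits(segs[[1]]$yolk, "labeled_region"))
  expect_true("cardinality_suspect" %in% segs[[1]]$flags)
})

test_that("egg mode validates only shells: holes filled, edge eggs dropped", {
  shell <- disc_mask(shape, 50, 60, 25) & !disc_mask(shape, 50, 60, 22)
  stray_yolk <- disc_mask(shape, 50, 60, 6)
  edge_egg <- disc_mask(shape, 2, 20, 8)    # touches border after fill
  edge_egg[1, ] <- FALSE; edge_egg[1, 18:22] <- TRUE
  segs <- postprocess(list(region_of("egg", shell), region_of("yolk", stray_yolk),
                           region_of("egg", edge_egg)), shape, "egg")
  expect_length(segs, 1L)
  # the shell ring was filled to a solid disc
  expect_equal(segs[[1]]$body$area_px, sum(disc_mask(shape, 50, 60, 25)))
  expect_equal(segs[[1]]$body$feature_class, "egg")
})

test_that("two-lobed merged-eye regions are flagged by low solidity", {
  lobe1 <- disc_mask(shape, 50, 45, 9)
  lobe2 <- disc_mask(shape, 50, 75, 9)
  bridge <- rect_mask(shape, 49, 51, 45, 75)
  fig8 <- lobe1 | lobe2 | bridge
  body <- region_of("body", disc_mask(shape, 50, 60, 40))
  segs <- associate_parts(list(body), list(region_of("eye", fig8)))
  expect_true("eye_shape_suspect" %in% segs[[1]]$flags)
  # a clean single eye is not flagged
  segs2 <- associate_parts(list(body), list(region_of("eye", disc_mask(shape, 50, 60, 9))))
  expect_false("eye_shape_suspect" %in% segs2[[1]]$flags)
})
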