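# Synthetic scene and stream generator. Emulates the flow-through imaging
# appearance: dark larvae/eggs on a bright back-lit background (~220
# counts), rendered in 2-D orthographic projection (telecentric lens), with
# additive Gaussian sensor noise. Every rendered object carries exact
# ground-truth masks and analytic morphometrics, so parameter-recovery tests
# can close the loop from generator truth to measured values.
#
# Default magnitudes follow the study population: standard length
# 4.48 +/- 0.36 mm, body area ~1.43 mm^2, yolk sac 0.60 x 0.30 mm (prolate
# volume ~0.028 mm^3), eye diameter 0.286 mm, egg diameter 1.36 +/- 0.02 mm,
# at a default pixel scale of 8.8 mm field-of-view width / 2448 px =
# 0.0036 mm/px.

#' Parametric larva specification
#'
#' The body is a tube swept along a constant-curvature spine, with a
#' half-width profile tapering linearly from `head_halfwidth_mm` at the
#' snout to `tail_frac` of it at the tail, closed by circular caps. True
#' standard length is the spine arc length plus the two cap radii; true
#' projected area is the analytic swept area plus the half-disc caps.
#'
#' @param length_mm true standard length (snout to tail tip).
#' @param head_halfwidth_mm body half-width at the head.
#' @param tail_frac tail half-width as a fraction of the head half-width.
#' @param turn_rad total spine turning angle (0 = straight, `pi` =
#'   semicircular pose).
#' @param angle_rad overall orientation in the image plane.
#' @param center_mm `(row, col)` position of the body centroid in mm;
#'   `NULL` centres in the frame.
#' @param n_eyes 0, 1 (typical side-on view) or 2.
#' @param eye_diameter_mm,eye_length_mm eye minor/major axes.
#' @param eye_pos_frac eye centre position along the spine (fraction of arc).
#' @param yolk_length_mm,yolk_width_mm yolk-sac axes (0 disables the yolk).
#' @param yolk_pos_frac yolk centre position along the spine.
#' @param body_contrast,yolk_contrast,eye_contrast counts below background.
#' @return a `larva_spec` object.
#' @export
larva_spec <- function(length_mm = 4.48, head_halfwidth_mm = 0.255,
                       tail_frac = 0.25, turn_rad = 0, angle_rad = 0,
                       center_mm = NULL, n_eyes = 1L,
                       eye_diameter_mm = 0.286, eye_length_mm = 0.30,
                       eye_pos_frac = 0.08,
                       yolk_length_mm = 0.60, yolk_width_mm = 0.30,
                       yolk_pos_frac = 0.28,
                       body_contrast = 60, yolk_contrast = 100,
                       eye_contrast = 190) {
  stopifnot(length_mm > 0, head_halfwidth_mm > 0,
            tail_frac > 0, tail_frac <= 1,
            eye_diameter_mm <= eye_length_mm || n_eyes == 0L,
            yolk_width_mm <= yolk_length_mm || yolk_length_mm == 0)
  r_head <- head_halfwidth_mm
  r_tail <- tail_frac * r_head
  spine_len <- length_mm - r_head - r_tail
  if (spine_len <= 0) stop("`length_mm` too small for the width profile", call. = FALSE)
  structure(list(length_mm = length_mm, head_halfwidth_mm = r_head,
                 tail_halfwidth_mm = r_tail, tail_frac = tail_frac,
                 spine_len_mm = spine_len,
                 turn_rad = turn_rad, angle_rad = angle_rad,
                 center_mm = center_mm, n_eyes = as.integer(n_eyes),
                 eye_diameter_mm = eye_diameter_mm,
                 eye_length_mm = eye_length_mm, eye_pos_frac = eye_pos_frac,
                 yolk_length_mm = yolk_length_mm,
                 yolk_width_mm = yolk_width_mm, yolk_pos_frac = yolk_pos_frac,
                 body_contrast = body_contrast, yolk_contrast = yolk_contrast,
                 eye_contrast = eye_contrast),
            class = "larva_spec")
}

#' Parametric egg specification
#'
#' A near-spherical egg: dark shell ring around a faintly darkened interior.
#'
#' @param diameter_mm true egg diameter.
#' @param center_mm `(row, col)` centre in mm; `NULL` centres in the frame.
#' @param shell_contrast,interior_contrast counts below background.
#' @param shell_thickness_mm shell ring thickness.
#' @return an `egg_spec` object.
#' @export
egg_spec <- function(diameter_mm = 1.36, center_mm = NULL,
                     shell_contrast = 120, interior_contrast = 40,
                     shell_thickness_mm = 0.03) {
  stopifnot(diameter_mm > 0)
  structure(list(diameter_mm = diameter_mm, center_mm = center_mm,
                 shell_contrast = shell_contrast,
                 interior_contrast = interior_contrast,
                 shell_thickness_mm = shell_thickness_mm),
            class = "egg_spec")
}

# -- spine geometry -----------------------------------------------------

# Constant-curvature spine sampled at ~`spacing_mm`; heading is centred on
# `angle_rad` so the overall orientation is pose-controlled.
spine_points <- function(spec, spacing_mm) {
  L <- spec$spine_len_mm
  n <- max(3L, ceiling(L / spacing_mm) + 1L)
  s <- seq(0, L, length.out = n)
  k <- spec$turn_rad / L
  a0 <- spec$angle_rad - spec$turn_rad / 2
  if (abs(spec$turn_rad) < 1e-9) {
    col <- s * cos(a0); row <- s * sin(a0)
    tang <- cbind(drow = rep(sin(a0), n), dcol = rep(cos(a0), n))
  } else {
    col <- (sin(a0 + k * s) - sin(a0)) / k
    row <- -(cos(a0 + k * s) - cos(a0)) / k
    tang <- cbind(drow = sin(a0 + k * s), dcol = cos(a0 + k * s))
  }
  list(s = s, pts = cbind(row = row, col = col), tang = tang)
}

# Linear half-width profile along the spine.
spine_halfwidth <- function(spec, s) {
  t <- s / spec$spine_len_mm
  spec$head_halfwidth_mm * (1 - (1 - spec$tail_frac) * t)
}

#' Analytic ground truth for a larva specification
#'
#' @param spec a [larva_spec()].
#' @return list with `sl_mm` (spine arc plus caps), `area_mm2` (swept strip
#'   plus half-disc caps), organ axes, and model volumes evaluated from the
#'   true measurements.
#' @export
larva_truth <- function(spec) {
  L <- spec$spine_len_mm
  mean_r <- (spec$head_halfwidth_mm + spec$tail_halfwidth_mm) / 2
  area <- 2 * mean_r * L +
    pi / 2 * (spec$head_halfwidth_mm^2 + spec$tail_halfwidth_mm^2)
  vol <- larva_total_volume(area, spec$length_mm)
  yolk_vol <- if (spec$yolk_length_mm > 0)
    prolate_spheroid_volume(spec$yolk_width_mm, spec$yolk_length_mm) else NA_real_
  eye_vol <- if (spec$n_eyes > 0L)
    prolate_spheroid_volume(spec$eye_diameter_mm, spec$eye_length_mm) else NA_real_
  list(sl_mm = spec$length_mm, area_mm2 = area, total_volume_mm3 = vol,
       yolk_length_mm = if (spec$yolk_length_mm > 0) spec$yolk_length_mm else NA_real_,
       yolk_width_mm = if (spec$yolk_length_mm > 0) spec$yolk_width_mm else NA_real_,
       yolk_volume_mm3 = yolk_vol,
       structural_volume_mm3 = if (!is.na(yolk_vol)) vol - yolk_vol else NA_real_,
       eye_diameter_mm = if (spec$n_eyes > 0L) spec$eye_diameter_mm else NA_real_,
       eye_length_mm = if (spec$n_eyes > 0L) spec$eye_length_mm else NA_real_,
       eye_volume_mm3 = eye_vol)
}

# -- low-level rasterization -------------------------------------------

# Stamp a filled disc (centre and radius in px) into a logical matrix.
stamp_disc <- function(mask, r0, c0, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  rlo <- max(1, floor(r0 - radius)); rhi <- min(nr, ceiling(r0 + radius))
  clo <- max(1, floor(c0 - radius)); chi <- min(nc, ceiling(c0 + radius))
  if (rlo > rhi || clo > chi) return(mask)
  rr <- rlo:rhi; cc <- clo:chi
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  mask[rr, cc] <- mask[rr, cc] | (d2 <= radius^2)
  mask
}

# Filled rotated ellipse (px units, semi-axes a >= b, angle of major axis
# from the column axis).
rasterize_ellipse <- function(shape, r0, c0, a, b, angle) {
  nr <- shape[1]; nc <- shape[2]
  ext <- a + 1
  mask <- matrix(FALSE, nr, nc)
  rlo <- max(1, floor(r0 - ext)); rhi <- min(nr, ceiling(r0 + ext))
  clo <- max(1, floor(c0 - ext)); chi <- min(nc, ceiling(c0 + ext))
  if (rlo > rhi || clo > chi) return(mask)
  rr <- rlo:rhi; cc <- clo:chi
  dy <- matrix(rr - r0, length(rr), length(cc))
  dx <- matrix(cc - c0, length(rr), length(cc), byrow = TRUE)
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  mask[rr, cc] <- (u / a)^2 + (v / b)^2 <= 1
  mask
}

# -- scene rendering ----------------------------------------------------

# Draw one larva onto a canvas; returns updated canvas plus truth regions.
draw_larva <- function(canvas, spec, scale, background) {
  s <- as_scale(scale)$mm_per_px
  shape <- dim(canvas)
  ctr <- spec$center_mm %||% (c(shape[1], shape[2]) / 2 * s)
  # 2 px stamp spacing: scalloping depth r - sqrt(r^2 - 1) is < 0.05 px for
  # the body half-widths in use
  sp <- spine_points(spec, spacing_mm = 2 * s)
  # centre the spine's bounding box midpoint on ctr
  mid <- (apply(sp$pts, 2, max) + apply(sp$pts, 2, min)) / 2
  pts_mm <- sweep(sp$pts, 2, mid) + rep(ctr, each = nrow(sp$pts))
  pts_px <- pts_mm / s
  radii_px <- spine_halfwidth(spec, sp$s) / s
  body <- .stamp_discs(shape[1], shape[2], pts_px[, 1], pts_px[, 2], radii_px)
  organ_at <- function(frac, a_mm, b_mm) {
    si <- which.min(abs(sp$s - frac * spec$spine_len_mm))
    ang <- atan2(sp$tang[si, 1], sp$tang[si, 2])
    rasterize_ellipse(shape, pts_px[si, 1], pts_px[si, 2],
                      a_mm / 2 / s, b_mm / 2 / s, ang)
  }
  eyes <- list()
  if (spec$n_eyes >= 1L)
    eyes <- c(eyes, list(organ_at(spec$eye_pos_frac,
                                  spec$eye_length_mm, spec$eye_diameter_mm)))
  if (spec$n_eyes >= 2L)
    eyes <- c(eyes, list(organ_at(spec$eye_pos_frac + 0.10,
                                  spec$eye_length_mm, spec$eye_diameter_mm)))
  yolk <- NULL
  if (spec$yolk_length_mm > 0)
    yolk <- organ_at(spec$yolk_pos_frac, spec$yolk_length_mm, spec$yolk_width_mm)
  for (e in eyes) body <- body | e
  if (!is.null(yolk)) body <- body | yolk
  canvas[body] <- pmin(canvas[body], background - spec$body_contrast)
  if (!is.null(yolk)) canvas[yolk] <- pmin(canvas[yolk], background - spec$yolk_contrast)
  for (e in eyes) canvas[e] <- pmin(canvas[e], background - spec$eye_contrast)
  regions <- list(labeled_region("body", body, confidence = 1))
  for (e in eyes) regions <- c(regions, list(labeled_region("eye", e, confidence = 1)))
  if (!is.null(yolk)) regions <- c(regions, list(labeled_region("yolk", yolk, confidence = 1)))
  # true snout/tail positions (px): spine ends extended through the caps
  head_px <- pts_px[1, ] - sp$tang[1, c("drow", "dcol")] * spec$head_halfwidth_mm / s
  tail_px <- pts_px[nrow(pts_px), ] +
    sp$tang[nrow(pts_px), c("drow", "dcol")] * spec$tail_halfwidth_mm / s
  truth <- c(larva_truth(spec),
             list(head_px = head_px, tail_px = tail_px,
                  off_frame = touches_border(body)))
  list(canvas = canvas, regions = regions, truth = truth)
}

draw_egg <- function(canvas, spec, scale, background) {
  s <- as_scale(scale)$mm_per_px
  shape <- dim(canvas)
  r_px <- spec$diameter_mm / 2 / s
  if (2 * r_px < 2) stop("egg diameter below the 2 px resolution floor", call. = FALSE)
  ctr <- spec$center_mm %||% (c(shape[1], shape[2]) / 2 * s)
  ctr_px <- ctr / s
  disc <- stamp_disc(matrix(FALSE, shape[1], shape[2]),
                     ctr_px[1], ctr_px[2], r_px)
  inner <- stamp_disc(matrix(FALSE, shape[1], shape[2]), ctr_px[1], ctr_px[2],
                      max(0, r_px - spec$shell_thickness_mm / s))
  ring <- disc & !inner
  canvas[inner] <- pmin(canvas[inner], background - spec$interior_contrast)
  canvas[ring] <- pmin(canvas[ring], background - spec$shell_contrast)
  truth <- list(diameter_mm = spec$diameter_mm,
                volume_mm3 = egg_volume(spec$diameter_mm),
                center_px = ctr_px, radius_px = r_px,
                off_frame = touches_border(disc))
  list(canvas = canvas, regions = list(labeled_region("egg", disc, confidence = 1)),
       truth = truth)
}

#' Render a synthetic scene
#'
#' Composites any mix of [larva_spec()] / [egg_spec()] objects onto a bright
#' back-lit background, adds clipped Gaussian sensor noise, and returns the
#' exact truth masks and analytic morphometrics of every object. Overlapping
#' objects darken jointly (minimum intensity wins); overlaps are visible in
#' the truth masks.
#'
#' @param specs a single spec or a list of specs.
#' @param scale a [px_scale()] or mm/px number (default 0.0036).
#' @param image_shape `c(height, width)` in px.
#' @param seed RNG seed for the noise (deterministic rendering).
#' @param noise_sd Gaussian noise standard deviation in counts (default 5).
#' @param background background intensity in counts (default 220).
#' @return a `synthetic_scene`: `image` (h x w matrix, 0-255), `regions`
#'   (flat list of truth [labeled_region()]s), `objects` (per-object truth),
#'   `scale`, `background`.
#' @export
render_scene <- function(specs, scale = px_scale(0.0036),
                         image_shape = c(900, 1500), seed = 1L,
                         noise_sd = 5, background = 220) {
  if (inherits(specs, "larva_spec") || inherits(specs, "egg_spec"))
    specs <- list(specs)
  canvas <- matrix(background, image_shape[1], image_shape[2])
  regions <- list(); objects <- list()
  for (sp in specs) {
    drawn <- if (inherits(sp, "larva_spec"))
      draw_larva(canvas, sp, scale, background)
    else draw_egg(canvas, sp, scale, background)
    canvas <- drawn$canvas
    regions <- c(regions, drawn$regions)
    objects <- c(objects, list(drawn$truth))
  }
  if (noise_sd > 0) {
    canvas <- canvas + with_preserved_seed(seed,
      matrix(rnorm(length(canvas), 0, noise_sd), nrow(canvas)))
  }
  canvas <- pmin(pmax(canvas, 0), 255)
  structure(list(image = canvas, regions = regions, objects = objects,
                 scale = as_scale(scale), background = background),
            class = "synthetic_scene")
}

#' @rdname render_scene
#' @param spec a single [larva_spec()].
#' @export
render_larva <- function(spec = larva_spec(), scale = px_scale(0.0036),
                         image_shape = c(900, 1500), seed = 1L,
                         noise_sd = 5, background = 220) {
  render_scene(list(spec), scale, image_shape, seed, noise_sd, background)
}

#' @rdname render_scene
#' @export
render_egg <- function(spec = egg_spec(), scale = px_scale(0.0036),
                       image_shape = c(600, 600), seed = 1L,
                       noise_sd = 5, background = 220) {
  render_scene(list(spec), scale, image_shape, seed, noise_sd, background)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d px, %d objects, %d truth regions\n",
              nrow(x$image), ncol(x$image), length(x$objects), length(x$regions)))
  invisible(x)
}

#' Render a synthetic frame stream
#'
#' A background with slow sinusoidal intensity drift plus per-frame noise;
#' dark discs appear only at scheduled frames (super-threshold objects), and
#' optional small distractor blobs (bubbles, fibres) below the minimum-area
#' filter appear at random frames. The truth records exactly which frames
#' contain super-threshold objects.
#'
#' @param n_frames stream length.
#' @param injection_frames frame indices receiving one large object each.
#' @param n_distractors number of small distractor blobs.
#' @param image_shape `c(height, width)`.
#' @param scale a [px_scale()] or mm/px number.
#' @param object_diameter_mm diameter of injected objects.
#' @param object_contrast counts below background for injected objects.
#' @param distractor_diameter_mm diameter of distractors (keep their area
#'   under the selection `min_area_mm2`).
#' @param distractor_contrast counts below background for distractors.
#' @param drift_amplitude,drift_period sinusoidal background drift (counts,
#'   frames).
#' @param background,noise_sd background level and noise SD in counts.
#' @param seed RNG seed (positions, noise); fixed seed reproduces the stream
#'   bit-identically.
#' @return list with `stream` (a [frame_stream()]) and `truth`
#'   (`selected_frames`, `distractor_frames`, object positions).
#' @export
render_stream <- function(n_frames = 200, injection_frames = integer(),
                          n_distractors = 0, image_shape = c(120, 160),
                          scale = px_scale(0.01),
                          object_diameter_mm = 0.7, object_contrast = 80,
                          distractor_diameter_mm = 0.15,
                          distractor_contrast = 80,
                          drift_amplitude = 3, drift_period = 120,
                          background = 220, noise_sd = 5, seed = 1L) {
  stopifnot(all(injection_frames >= 1), all(injection_frames <= n_frames))
  s <- as_scale(scale)$mm_per_px
  h <- image_shape[1]; w <- image_shape[2]
  r_obj <- object_diameter_mm / 2 / s
  r_dis <- distractor_diameter_mm / 2 / s
  if (length(injection_frames) > 0 && 2 * r_obj + 4 >= min(h, w))
    stop("objects of this diameter do not fit the frame", call. = FALSE)
  if (n_distractors > 0 && 2 * r_dis + 4 >= min(h, w))
    stop("distractors of this diameter do not fit the frame", call. = FALSE)
  with_preserved_seed(seed, {
    pos <- cbind(runif(length(injection_frames), r_obj + 2, h - r_obj - 2),
                 runif(length(injection_frames), r_obj + 2, w - r_obj - 2))
    dis_frames <- if (n_distractors > 0) sample.int(n_frames, n_distractors,
                                                    replace = TRUE) else integer()
    dpos <- cbind(runif(n_distractors, r_dis + 2, h - r_dis - 2),
                  runif(n_distractors, r_dis + 2, w - r_dis - 2))
    pixels <- array(0, dim = c(h, w, n_frames))
    for (i in seq_len(n_frames)) {
      fr <- matrix(background + drift_amplitude * sin(2 * pi * i / drift_period),
                   h, w)
      ks <- which(injection_frames == i)
      for (k in ks) {
        m <- stamp_disc(matrix(FALSE, h, w), pos[k, 1], pos[k, 2], r_obj)
        fr[m] <- fr[m] - object_contrast
      }
      kd <- which(dis_frames == i)
      for (k in kd) {
        m <- stamp_disc(matrix(FALSE, h, w), dpos[k, 1], dpos[k, 2], r_dis)
        fr[m] <- fr[m] - distractor_contrast
      }
      if (noise_sd > 0) fr <- fr + matrix(rnorm(h * w, 0, noise_sd), h, w)
      pixels[, , i] <- pmin(pmax(fr, 0), 255)
    }
    list(stream = frame_stream(pixels),
         truth = list(selected_frames = sort(unique(as.integer(injection_frames))),
                      distractor_frames = sort(unique(as.integer(dis_frames))),
                      object_positions = pos))
  })
}

#' Curated scenario suite
#'
#' Clean scenes plus the documented failure modes of flow-through imaging:
#' a body clipped by the frame edge (body discarded, organs retained), two
#' overlapping larvae and two touching larvae (merged body segmentation,
#' invalid), an excessively curled pose (beyond a semicircle, length
#' unreliable), and a larva imaged from above (no visible yolk; the two
#' eyes merge into a single figure-8 region). Each scene carries the truth
#' and the validity flags the pipeline is expected to assign.
#'
#' @param seed RNG seed; clean-scene lengths are drawn from
#'   Normal(4.48, 0.36) mm, the study population's standard-length
#'   distribution.
#' @param n_clean number of clean scenes.
#' @param scale a [px_scale()] or mm/px number.
#' @param image_shape `c(height, width)`.
#' @param noise_sd noise SD in counts.
#' @return list of scenarios: each has `name`, `scene` (a
#'   [render_scene()] result), and `expected` (named logical vector of
#'   validity flags, `NA` = unchecked).
#' @export
scenario_suite <- function(seed = 1L, n_clean = 6, scale = px_scale(0.0036),
                           image_shape = c(900, 1500), noise_sd = 5) {
  s <- as_scale(scale)$mm_per_px
  draw <- with_preserved_seed(seed, list(
    lens = pmax(3.4, pmin(5.2, rnorm(n_clean, 4.48, 0.36))),
    turns = runif(n_clean, 0, pi / 2),
    eye_d = pmax(0.25, pmin(0.32, rnorm(n_clean, 0.286, 0.004))),
    yolk_l = pmax(0.45, pmin(0.75, rnorm(n_clean, 0.60, 0.05))),
    yolk_w = pmax(0.22, pmin(0.38, rnorm(n_clean, 0.30, 0.025)))))
  out <- list()
  for (i in seq_len(n_clean)) {
    sc <- render_scene(
      larva_spec(length_mm = draw$lens[i], turn_rad = draw$turns[i],
                 eye_diameter_mm = draw$eye_d[i],
                 eye_length_mm = draw$eye_d[i] + 0.015,
                 yolk_length_mm = draw$yolk_l[i],
                 yolk_width_mm = min(draw$yolk_w[i], draw$yolk_l[i] - 0.05)),
      scale, image_shape, seed = seed + 10L + i, noise_sd = noise_sd)
    out[[length(out) + 1L]] <- list(
      name = sprintf("clean_%02d", i), scene = sc,
      expected = c(body_valid = TRUE, eyes_valid = TRUE, yolk_valid = TRUE))
  }
  # tail clipped by the frame edge; head organs on the interior side
  edge <- larva_spec(center_mm = c(image_shape[1] / 2 * s, 1.4),
                     angle_rad = pi)
  sc <- render_scene(edge, scale, image_shape, seed = seed + 101L,
                     noise_sd = noise_sd)
  out[[length(out) + 1L]] <- list(
    name = "edge_clipped", scene = sc,
    expected = c(body_valid = FALSE, eyes_valid = TRUE, yolk_valid = TRUE))
  # two larvae crossing
  ctr <- c(image_shape[1], image_shape[2]) / 2 * s
  sc <- render_scene(list(
    larva_spec(angle_rad = 0, center_mm = ctr),
    larva_spec(angle_rad = pi / 5, center_mm = ctr)),
    scale, image_shape, seed = seed + 102L, noise_sd = noise_sd)
  out[[length(out) + 1L]] <- list(
    name = "overlapping_larvae", scene = sc,
    expected = c(body_valid = FALSE, eyes_valid = NA, yolk_valid = NA))
  # two larvae touching end to end (shorter individuals so the pair fits)
  sc <- render_scene(list(
    larva_spec(length_mm = 2.6, center_mm = ctr - c(0, 1.18)),
    larva_spec(length_mm = 2.6, center_mm = ctr + c(0, 1.18),
               angle_rad = pi / 36)),
    scale, image_shape, seed = seed + 103L, noise_sd = noise_sd)
  out[[length(out) + 1L]] <- list(
    name = "touching_larvae", scene = sc,
    expected = c(body_valid = FALSE, eyes_valid = NA, yolk_valid = NA))
  # excessively curled pose (well beyond a semicircle)
  sc <- render_scene(larva_spec(turn_rad = 1.7 * pi), scale, image_shape,
                     seed = seed + 104L, noise_sd = noise_sd)
  out[[length(out) + 1L]] <- list(
    name = "curled", scene = sc,
    expected = c(body_valid = FALSE, eyes_valid = NA, yolk_valid = NA))
  # dorsal (top-down) view: narrow body, no yolk, merged figure-8 eyes
  sc <- render_dorsal_scene(scale, image_shape, seed = seed + 105L,
                            noise_sd = noise_sd)
  out[[length(out) + 1L]] <- list(
    name = "dorsal_view", scene = sc,
    expected = c(body_valid = TRUE, eyes_valid = FALSE, yolk_valid = FALSE))
  out
}

# Top-down pose: slender straight body without yolk; the paired eyes sit
# side by side across the body axis and are joined by a dark bridge,
# emulating the merged figure-8 segmentation of partly overlapping eyes.
render_dorsal_scene <- function(scale, image_shape, seed, noise_sd,
                                background = 220) {
  s <- as_scale(scale)$mm_per_px
  spec <- larva_spec(head_halfwidth_mm = 0.16, tail_frac = 0.3,
                     yolk_length_mm = 0, n_eyes = 0L)
  canvas <- matrix(background, image_shape[1], image_shape[2])
  drawn <- draw_larva(canvas, spec, scale, background)
  canvas <- drawn$canvas
  body <- drawn$regions[[1]]$mask
  # eye pair: lobes offset across the axis near the head, plus a bridge
  sp <- spine_points(spec, spacing_mm = s)
  mid <- (apply(sp$pts, 2, max) + apply(sp$pts, 2, min)) / 2
  ctr <- c(image_shape[1], image_shape[2]) / 2 * s
  p_head <- (sp$pts[which.min(abs(sp$s - 0.08 * spec$spine_len_mm)), ] - mid + ctr) / s
  r_eye <- 0.06 / s
  off <- 0.11 / s
  e1 <- stamp_disc(matrix(FALSE, image_shape[1], image_shape[2]),
                   p_head[1] - off, p_head[2], r_eye)
  e2 <- stamp_disc(matrix(FALSE, image_shape[1], image_shape[2]),
                   p_head[1] + off, p_head[2], r_eye)
  bridge <- matrix(FALSE, image_shape[1], image_shape[2])
  rr <- max(1, round(p_head[1] - off)):min(image_shape[1], round(p_head[1] + off))
  cc <- pmax(1, pmin(image_shape[2], round(p_head[2] + c(-1, 0, 1))))
  bridge[rr, cc] <- TRUE
  eye <- e1 | e2 | bridge
  body <- body | eye
  canvas[body] <- pmin(canvas[body], background - spec$body_contrast)
  canvas[eye] <- pmin(canvas[eye], background - spec$eye_contrast)
  if (noise_sd > 0) {
    canvas <- canvas + with_preserved_seed(seed,
      matrix(rnorm(length(canvas), 0, noise_sd), nrow(canvas)))
  }
  canvas <- pmin(pmax(canvas, 0), 255)
  truth <- drawn$truth
  truth$merged_eyes <- TRUE
  structure(list(image = canvas,
                 regions = list(labeled_region("body", body, confidence = 1),
                                labeled_region("eye", eye, confidence = 1)),
                 objects = list(truth), scale = as_scale(scale),
                 background = background),
            class = "synthetic_scene")
}
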