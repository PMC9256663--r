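# Per-individual morphometrics from validated segmentations: standard
# length along the extracted centerline, facing direction from terminal
# body widths, second-moment major/minor axes of eyes and yolk sac, and
# projected areas (pixel counts, unsmoothed, converted through the pixel
# scale).

#' Standard length from a centerline
#'
#' @param centerline an [extract_centerline()] result.
#' @param scale a [px_scale()] or mm/px number.
#' @return standard length in mm.
#' @export
standard_length <- function(centerline, scale) {
  stopifnot(inherits(centerline, "centerline"))
  to_mm(centerline$arc_length_px, scale)
}

#' Facing direction of a larva
#'
#' Heads are wider than tails: the head end is the centerline end whose mean
#' inscribed body width over the terminal 20% of arc length is larger. The
#' heading is the unit vector from tail endpoint to head endpoint. When the
#' two terminal widths differ by less than a factor 1.1 the heading is
#' flagged ambiguous (e.g. a symmetric capsule).
#'
#' @param body_mask logical matrix.
#' @param centerline an [extract_centerline()] result for that mask.
#' @return list with `heading` (`c(drow, dcol)`, unit), `head`, `tail`
#'   (endpoints), `width_ratio`, `ambiguous`.
#' @export
facing_direction <- function(body_mask, centerline) {
  stopifnot(inherits(centerline, "centerline"))
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(body_mask * 1)))
  pts <- centerline$points
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  wid <- function(sel) {
    p <- pts[sel, , drop = FALSE]
    rp <- pmin(pmax(round(p[, 1]), 1), nrow(body_mask))
    cp <- pmin(pmax(round(p[, 2]), 1), ncol(body_mask))
    mean(2 * dm[cbind(rp, cp)])
  }
  w_first <- wid(cum <= 0.2 * L)
  w_last <- wid(cum >= 0.8 * L)
  ratio <- max(w_first, w_last) / max(min(w_first, w_last), .Machine$double.eps)
  if (w_first >= w_last) { head <- pts[1L, ]; tail_ <- pts[nrow(pts), ] }
  else { head <- pts[nrow(pts), ]; tail_ <- pts[1L, ] }
  v <- unname(head - tail_)
  v <- v / sqrt(sum(v^2))
  list(heading = c(drow = v[1], dcol = v[2]), head = unname(head),
       tail = unname(tail_), width_ratio = ratio, ambiguous = ratio < 1.1)
}

#' Major and minor axes of a region
#'
#' Axes of the ellipse with the same second central moments as the pixel
#' set, normalised so a solid ellipse returns its own full axis lengths
#' (`major = 4 sqrt(lambda_max)`). More robust to boundary noise than Feret
#' extents.
#'
#' @param region_mask logical matrix (or a [labeled_region()]).
#' @return list with `major_px`, `minor_px`, `orientation_rad` (angle of the
#'   major axis from the column axis, in `(-pi/2, pi/2]`), `degenerate`.
#' @export
measure_axes <- function(region_mask) {
  if (inherits(region_mask, "labeled_region")) region_mask <- region_mask$mask
  idx <- which(region_mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) stop("empty region", call. = FALSE)
  if (n == 1L) {
    return(list(major_px = 1, minor_px = 1, orientation_rad = 0,
                degenerate = TRUE))
  }
  y <- idx[, 1]; x <- idx[, 2]
  mu20 <- mean((x - mean(x))^2)
  mu02 <- mean((y - mean(y))^2)
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc; l2 <- max(0, tr / 2 - disc)
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  list(major_px = 4 * sqrt(l1), minor_px = 4 * sqrt(l2),
       orientation_rad = theta, degenerate = FALSE)
}

#' Measure one validated individual
#'
#' Larva mode: standard length from the centerline, body area (pixel count
#' times scale squared), eye and yolk axes/areas, facing direction, volumes
#' via the closed-form models, and per-feature validity flags. With no body
#' (edge-discarded) the organ measurements are still produced and
#' `body_valid` is `FALSE`. Egg mode: egg-shell axes, mean diameter, radius,
#' spherical volume, circularity; embryo-body and yolk fields are never
#' emitted.
#'
#' Reported eye diameter is the measured width (minor axis) `W_E`; eye and
#' yolk volumes use the prolate-spheroid model. When two eyes are retained
#' the reported eye measurements are their means (`n_eyes` records the
#' count). Bodies flagged `cardinality_suspect` (more organ candidates than
#' one fish can carry: merged/touching fish), `curvature_suspect` (centerline
#' turning angle beyond `max_turn_rad`) or `low_elongation` are reported with
#' `body_valid = FALSE`; their numbers are retained for audit.
#'
#' @param seg a `fish_segmentation` from [postprocess()].
#' @param scale a [px_scale()] or mm/px number.
#' @param mode `"larva"` or `"egg"`.
#' @param frame_id,seg_id identifiers copied into the output row.
#' @param max_turn_rad curvature flag threshold (default `1.25 * pi`; a
#'   semicircular pose turns by exactly `pi` and is still measurable).
#' @param eccentricity_warn egg-mode circularity below which
#'   `eccentric_egg` is flagged (default 0.95).
#' @return a one-row data.frame ([larva_record()] / [egg_record()] columns).
#' @export
measure_individual <- function(seg, scale, mode = c("larva", "egg"),
                               frame_id = NA_integer_, seg_id = NA_integer_,
                               max_turn_rad = 1.25 * pi,
                               eccentricity_warn = 0.95) {
  mode <- match.arg(mode)
  scale <- as_scale(scale)
  if (mode == "egg") {
    return(measure_egg(seg, scale, frame_id, seg_id, eccentricity_warn))
  }
  flags <- seg$flags
  rec <- larva_record(frame_id, seg_id)

  if (!is.null(seg$body)) {
    cl <- extract_centerline(seg$body$mask)
    flags <- c(flags, cl$flags)
    turn <- centerline_turning_angle(cl)
    if (turn > max_turn_rad) flags <- c(flags, "curvature_suspect")
    rec$standard_length_mm <- standard_length(cl, scale)
    rec$body_area_mm2 <- to_mm2(seg$body$area_px, scale)
    rec$total_volume_mm3 <- larva_total_volume(rec$body_area_mm2,
                                               rec$standard_length_mm)
    fd <- facing_direction(seg$body$mask, cl)
    rec$facing_drow <- fd$heading[1]
    rec$facing_dcol <- fd$heading[2]
    rec$facing_ambiguous <- fd$ambiguous
    rec$body_valid <- !any(c("cardinality_suspect", "curvature_suspect",
                             "low_elongation") %in% flags)
  } else {
    rec$body_valid <- FALSE
  }

  if (length(seg$eyes) > 0L) {
    ax <- lapply(seg$eyes, function(e) measure_axes(e$mask))
    rec$n_eyes <- length(seg$eyes)
    rec$eye_length_mm <- to_mm(mean(vapply(ax, `[[`, numeric(1), "major_px")), scale)
    rec$eye_diameter_mm <- to_mm(mean(vapply(ax, `[[`, numeric(1), "minor_px")), scale)
    rec$eye_area_mm2 <- to_mm2(mean(vapply(seg$eyes, function(e) e$area_px,
                                           numeric(1))), scale)
    rec$eye_volume_mm3 <- prolate_spheroid_volume(rec$eye_diameter_mm,
                                                  rec$eye_length_mm)
    rec$eyes_valid <- !("eye_shape_suspect" %in% flags)
  }

  if (!is.null(seg$yolk)) {
    ax <- measure_axes(seg$yolk$mask)
    rec$yolk_length_mm <- to_mm(ax$major_px, scale)
    rec$yolk_width_mm <- to_mm(ax$minor_px, scale)
    rec$yolk_area_mm2 <- to_mm2(seg$yolk$area_px, scale)
    rec$yolk_volume_mm3 <- prolate_spheroid_volume(rec$yolk_width_mm,
                                                   rec$yolk_length_mm)
    rec$yolk_valid <- TRUE
  }

  if (!is.na(rec$total_volume_mm3) && !is.na(rec$yolk_volume_mm3)) {
    vs <- structural_volume(rec$total_volume_mm3, rec$yolk_volume_mm3)
    rec$structural_volume_mm3 <- vs$value
    if (vs$suspect) flags <- c(flags, "structural_volume_suspect")
  }
  rec$flags <- paste(unique(flags), collapse = ";")
  rec
}

#' Empty per-individual record rows
#'
#' Column templates for the measurement tables; all lengths in mm, areas in
#' mm^2, volumes in mm^3.
#'
#' @param frame_id,seg_id identifiers.
#' @return one-row data.frame.
#' @export
larva_record <- function(frame_id = NA_integer_, seg_id = NA_integer_) {
  data.frame(frame_id = frame_id, seg_id = seg_id, mode = "larva",
             body_valid = FALSE, eyes_valid = FALSE, yolk_valid = FALSE,
             n_eyes = 0L,
             standard_length_mm = NA_real_, body_area_mm2 = NA_real_,
             total_volume_mm3 = NA_real_,
             yolk_length_mm = NA_real_, yolk_width_mm = NA_real_,
             yolk_area_mm2 = NA_real_, yolk_volume_mm3 = NA_real_,
             structural_volume_mm3 = NA_real_,
             eye_length_mm = NA_real_, eye_diameter_mm = NA_real_,
             eye_area_mm2 = NA_real_, eye_volume_mm3 = NA_real_,
             facing_drow = NA_real_, facing_dcol = NA_real_,
             facing_ambiguous = NA, flags = "")
}

#' @rdname larva_record
#' @export
egg_record <- function(frame_id = NA_integer_, seg_id = NA_integer_) {
  data.frame(frame_id = frame_id, seg_id = seg_id, mode = "egg",
             egg_valid = FALSE,
             egg_major_mm = NA_real_, egg_minor_mm = NA_real_,
             egg_diameter_mm = NA_real_, egg_radius_mm = NA_real_,
             egg_volume_mm3 = NA_real_, circularity = NA_real_,
             flags = "")
}

measure_egg <- function(seg, scale, frame_id, seg_id, eccentricity_warn) {
  rec <- egg_record(frame_id, seg_id)
  flags <- seg$flags
  if (!is.null(seg$body)) {
    ax <- measure_axes(seg$body$mask)
    rec$egg_major_mm <- to_mm(ax$major_px, scale)
    rec$egg_minor_mm <- to_mm(ax$minor_px, scale)
    d <- egg_diameter(rec$egg_major_mm, rec$egg_minor_mm)
    rec$egg_diameter_mm <- d$diameter_mm
    rec$egg_radius_mm <- d$radius_mm
    rec$egg_volume_mm3 <- egg_volume(d$diameter_mm)
    rec$circularity <- rec$egg_minor_mm / rec$egg_major_mm
    if (rec$circularity < eccentricity_warn) flags <- c(flags, "eccentric_egg")
    rec$egg_valid <- TRUE
  }
  rec$flags <- paste(unique(flags), collapse = ";")
  rec
}
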