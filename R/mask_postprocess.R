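# Rule-based post-processing of raw instance segmentation masks. The
# enforced conditions for larvae: inner parts lie inside the body; at most
# one body, two eyes, one yolk sac per fish; no internal holes (filled);
# body and part bounds do not cross the image edges; eyes and yolk sacs are
# associated with a corresponding body. Application order: fill holes ->
# discard edge bodies -> associate parts (containment, then cardinality);
# hole-filling first makes containment meaningful, and discarding edge
# bodies before association lets interior organs survive the loss of their
# body.

#' Fill internal holes of a region
#'
#' Background components fully enclosed by the mask are added to it.
#' Concavities open to the image border are not enclosed and stay unfilled.
#' Idempotent; never decreases area.
#'
#' @param region a [labeled_region()] (or bare logical matrix).
#' @return same type as the input, hole-free.
#' @export
fill_holes <- function(region) {
  if (inherits(region, "labeled_region")) {
    out <- region
    filled <- fill_holes(region$mask)
    out$mask <- filled
    out$area_px <- sum(filled)
    out$bbox <- mask_bbox(filled)
    return(out)
  }
  out <- EBImage::imageData(EBImage::fillHull(EBImage::Image(region * 1))) != 0
  dim(out) <- dim(region)
  out
}

touches_border <- function(mask) {
  any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
}

#' Discard regions crossing the image edges
#'
#' Body regions with any pixel on the image border are removed (an off-frame
#' body cannot be measured); edge-touching eyes/yolks are removed
#' individually. Interior eyes and yolks are retained even when their body
#' was discarded — those measurements are still valid.
#'
#' @param regions list of [labeled_region()].
#' @param image_shape `c(height, width)` (used for validation only; masks are
#'   full-frame).
#' @return list with `kept` (regions), `body_discarded` (logical: was a body
#'   removed for edge contact), `discarded` (audit data.frame).
#' @export
discard_edge_bodies <- function(regions, image_shape = NULL) {
  kept <- list(); discarded <- list()
  body_discarded <- FALSE
  for (r in regions) {
    if (!is.null(image_shape) && !all(dim(r$mask) == image_shape))
      stop("region mask shape differs from image_shape", call. = FALSE)
    if (touches_border(r$mask)) {
      if (r$feature_class %in% c("body", "egg")) body_discarded <- TRUE
      discarded[[length(discarded) + 1L]] <-
        data.frame(feature_class = r$feature_class, area_px = r$area_px,
                   reason = "edge_contact")
    } else {
      kept[[length(kept) + 1L]] <- r
    }
  }
  list(kept = kept, body_discarded = body_discarded,
       discarded = if (length(discarded)) do.call(rbind, discarded) else
         data.frame(feature_class = character(), area_px = integer(),
                    reason = character()))
}

#' Enforce containment of inner parts inside the body
#'
#' A part (eye or yolk) is kept only when the number of its pixels outside
#' the body's filled mask is at most `slack` pixels. Retained parts are
#' unchanged.
#'
#' @param body a body [labeled_region()] (hole-free).
#' @param parts list of part regions.
#' @param slack allowed overhang in pixels (default 0).
#' @return the retained parts.
#' @export
enforce_containment <- function(body, parts, slack = 0) {
  stopifnot(inherits(body, "labeled_region"))
  Filter(function(p) sum(p$mask & !body$mask) <= slack, parts)
}

#' Enforce per-class cardinality limits
#'
#' A fish has at most one body, two eyes and one yolk sac. Survivors are the
#' top-k by confidence; ties break by larger area, then by upper-left-most
#' centroid (deterministic).
#'
#' @param candidates list of [labeled_region()] of one class.
#' @param class the class (`"body"`, `"eye"`, `"yolk"`, `"egg"`).
#' @param limits named vector of per-class limits.
#' @return list with `kept` and `n_excess` (how many were trimmed).
#' @export
enforce_cardinality <- function(candidates, class,
                                limits = c(body = 1L, eye = 2L, yolk = 1L, egg = 1L)) {
  k <- limits[[class]]
  if (length(candidates) <= k) return(list(kept = candidates, n_excess = 0L))
  conf <- vapply(candidates, function(r) ifelse(is.na(r$confidence), 0, r$confidence),
                 numeric(1))
  area <- vapply(candidates, function(r) r$area_px, numeric(1))
  cent <- t(vapply(candidates, region_centroid, numeric(2)))
  ord <- order(-conf, -area, cent[, 1], cent[, 2])
  list(kept = candidates[ord[seq_len(k)]],
       n_excess = length(candidates) - k)
}

#' Associate eyes and yolk sacs with bodies
#'
#' Each part goes to the body whose filled mask contains the largest fraction
#' of the part's pixels, provided that fraction exceeds 50%. While bodies
#' exist, unassigned parts are dropped. When no body exists in the frame —
#' typically because an off-frame body was edge-discarded — the orphan parts
#' form a bodiless segmentation whose organ measurements are retained (the
#' organs are still measurable even when the body is not), which also keeps
#' the whole validation pass idempotent.
#'
#' @param bodies list of body regions (hole-free, edge-checked).
#' @param parts list of eye/yolk regions.
#' @param body_discarded was a body removed for edge contact upstream
#'   (recorded as the bodiless record's `body_discarded_reason`).
#' @param slack containment slack in pixels (see [enforce_containment()]).
#' @return list of `fish_segmentation` objects.
#' @export
associate_parts <- function(bodies, parts, body_discarded = FALSE, slack = 0) {
  segs <- list()
  if (length(bodies) > 0L) {
    assigned <- vector("list", length(bodies))
    for (p in parts) {
      fr <- vapply(bodies, function(b) sum(p$mask & b$mask) / max(p$area_px, 1L),
                   numeric(1))
      j <- which.max(fr)
      if (length(j) && fr[j] > 0.5) {
        assigned[[j]] <- c(assigned[[j]], list(p))
      }
    }
    for (j in seq_along(bodies)) {
      segs[[length(segs) + 1L]] <-
        build_segmentation(bodies[[j]], assigned[[j]], slack = slack,
                           body_discarded_reason = "none")
    }
  } else if (length(parts) > 0L) {
    segs[[1L]] <- build_segmentation(
      NULL, parts, slack = slack,
      body_discarded_reason = if (body_discarded) "edge_contact" else "none")
  }
  segs
}

build_segmentation <- function(body, parts, slack = 0,
                               body_discarded_reason = "none") {
  parts <- parts %||% list()
  if (!is.null(body)) parts <- enforce_containment(body, parts, slack)
  eyes <- Filter(function(p) p$feature_class == "eye", parts)
  yolks <- Filter(function(p) p$feature_class == "yolk", parts)
  ce <- enforce_cardinality(eyes, "eye")
  cy <- enforce_cardinality(yolks, "yolk")
  flags <- character()
  if (ce$n_excess > 0L || cy$n_excess > 0L) flags <- c(flags, "cardinality_suspect")
  for (e in ce$kept) {
    if (region_solidity(e$mask) < 0.85) flags <- unique(c(flags, "eye_shape_suspect"))
  }
  structure(list(body = body, eyes = ce$kept,
                 yolk = if (length(cy$kept)) cy$kept[[1L]] else NULL,
                 body_discarded_reason = body_discarded_reason,
                 flags = flags),
            class = "fish_segmentation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fish_segmentation <- function(x, ...) {
  cat(sprintf("<fish_segmentation> body=%s eyes=%d yolk=%s%s%s\n",
              if (is.null(x$body)) "absent" else sprintf("%d px", x$body$area_px),
              length(x$eyes),
              if (is.null(x$yolk)) "absent" else sprintf("%d px", x$yolk$area_px),
              if (x$body_discarded_reason != "none")
                sprintf(" [body discarded: %s]", x$body_discarded_reason) else "",
              if (length(x$flags)) paste0(" flags: ", paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

#' Post-process raw segmentation regions into validated fish segmentations
#'
#' Larva mode applies, in order: hole filling, edge discard (bodies and parts
#' independently; interior organs survive an edge-discarded body), part
#' association with containment, and per-class cardinality limits. Egg mode
#' validates only egg-shell regions (embryo-body and yolk measurements in
#' egg images are unreliable and not used): shells are hole-filled and
#' edge-touching shells discarded. Idempotent.
#'
#' @param regions list of [labeled_region()].
#' @param image_shape `c(height, width)`.
#' @param mode `"larva"` or `"egg"`.
#' @param slack containment slack in pixels.
#' @return list of `fish_segmentation` (larva mode) or egg-shell segmentation
#'   objects (egg mode: `fish_segmentation` with the shell in `$body`).
#' @export
postprocess <- function(regions, image_shape, mode = c("larva", "egg"),
                        slack = 0) {
  mode <- match.arg(mode)
  if (length(regions) == 0L) return(list())
  regions <- lapply(regions, fill_holes)
  if (mode == "egg") {
    shells <- Filter(function(r) r$feature_class == "egg", regions)
    ed <- discard_edge_bodies(shells, image_shape)
    return(lapply(ed$kept, function(s)
      structure(list(body = s, eyes = list(), yolk = NULL,
                     body_discarded_reason = "none", flags = character()),
                class = "fish_segmentation")))
  }
  ed <- discard_edge_bodies(regions, image_shape)
  bodies <- Filter(function(r) r$feature_class == "body", ed$kept)
  cb <- enforce_cardinality(bodies, "body",
                            limits = c(body = length(bodies), eye = 2L,
                                       yolk = 1L, egg = 1L))
  parts <- Filter(function(r) r$feature_class %in% c("eye", "yolk"), ed$kept)
  associate_parts(cb$kept, parts, body_discarded = ed$body_discarded,
                  slack = slack)
}

# Re-extract the raw regions of a segmentation (used to test idempotence).
segmentation_regions <- function(segs) {
  out <- list()
  for (s in segs) {
    if (!is.null(s$body)) out <- c(out, list(s$body))
    out <- c(out, s$eyes)
    if (!is.null(s$yolk)) out <- c(out, list(s$yolk))
  }
  out
}
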