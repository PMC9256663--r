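# Candidate-frame selection: moving-average background subtraction followed
# by connected-blob filtering. Most frames of a flow-through stream are empty
# background; eggs and larvae appear as transient dark blobs.

#' Moving-average background model
#'
#' Estimates the static scene at one frame as the per-pixel mean over the
#' `window` frames nearest to it, excluding the frame itself (a transient
#' object must not suppress its own detection). The window is a contiguous
#' block shifted, not shrunk, at the stream ends, so its size is constant.
#'
#' @param stream a [frame_stream()].
#' @param index target frame (1-based).
#' @param window number of frames averaged (default 50).
#' @return an object of class `background_model` with fields `mean_image`,
#'   `window`, `frames_used` (the indices averaged).
#' @export
build_background <- function(stream, index, window = 50) {
  stopifnot(inherits(stream, "frame_stream"))
  n <- stream$n
  if (n < window + 1L) {
    stop(sprintf(paste0("stream has %d frames but the background window needs ",
                        "%d plus the target; use a smaller `window`"),
                 n, window), call. = FALSE)
  }
  if (index < 1L || index > n) stop("`index` out of range", call. = FALSE)
  idx <- background_window_indices(n, index, window)
  mean_image <- rowMeans(stream$pixels[, , idx, drop = FALSE], dims = 2L)
  structure(list(mean_image = mean_image, window = window, frames_used = idx),
            class = "background_model")
}

# Contiguous block of `window + 1` positions containing `index`, clamped to
# the stream, minus `index` itself. Ties (even windows) lean to earlier frames.
background_window_indices <- function(n, index, window) {
  lo <- index - ceiling(window / 2)
  lo <- max(1L, min(lo, n - window))
  hi <- lo + window
  setdiff(seq.int(lo, hi), index)
}

#' Foreground mask by background subtraction
#'
#' A pixel is foreground iff its absolute difference from the background mean
#' exceeds `threshold`. Back-lit imaging gives high, stable contrast, so a
#' fixed absolute threshold (default 25 of 255 counts) suffices; a global
#' additive intensity offset cancels in the subtraction.
#'
#' @param frame `h x w` intensity matrix.
#' @param bg a [build_background()] model (or a bare mean-image matrix).
#' @param threshold intensity difference in counts, `> 0`.
#' @return logical matrix.
#' @export
foreground_mask <- function(frame, bg, threshold = 25) {
  mean_image <- if (inherits(bg, "background_model")) bg$mean_image else bg
  if (!all(dim(frame) == dim(mean_image)))
    stop("frame and background shapes differ", call. = FALSE)
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  abs(frame - mean_image) > threshold
}

#' Detect blobs (connected foreground components)
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8: thin larva tails stay connected).
#' @return data.frame with one row per blob: `label`, `area_px`,
#'   `rmin,rmax,cmin,cmax`, `centroid_row`, `centroid_col`.
#' @export
detect_blobs <- function(mask, connectivity = 8) {
  lab <- label_components(mask, connectivity)
  nlab <- max(lab)
  if (nlab == 0L) return(empty_blob_table())
  idx <- which(lab > 0L, arr.ind = TRUE)
  l <- lab[lab > 0L]
  agg <- function(v, f) vapply(split(v, l), f, numeric(1))
  data.frame(label = as.integer(names(split(l, l))),
             area_px = as.integer(agg(l, length)),
             rmin = agg(idx[, 1], min), rmax = agg(idx[, 1], max),
             cmin = agg(idx[, 2], min), cmax = agg(idx[, 2], max),
             centroid_row = agg(idx[, 1], mean),
             centroid_col = agg(idx[, 2], mean),
             row.names = NULL)
}

empty_blob_table <- function() {
  data.frame(label = integer(), area_px = integer(),
             rmin = numeric(), rmax = numeric(),
             cmin = numeric(), cmax = numeric(),
             centroid_row = numeric(), centroid_col = numeric())
}

#' Filter blobs too small to be an egg or larva
#'
#' Keeps blobs with `area_px >= min_area` and both bounding-box sides
#' `>= min_bbox_side`. Order is preserved.
#'
#' @param blobs a [detect_blobs()] table.
#' @param min_area minimum pixel area.
#' @param min_bbox_side minimum bounding-box side in pixels.
#' @return the filtered table.
#' @export
filter_blobs <- function(blobs, min_area = 0, min_bbox_side = 0) {
  stopifnot(min_area >= 0, min_bbox_side >= 0)
  if (nrow(blobs) == 0L) return(blobs)
  keep <- blobs$area_px >= min_area &
    (blobs$rmax - blobs$rmin + 1) >= min_bbox_side &
    (blobs$cmax - blobs$cmin + 1) >= min_bbox_side
  blobs[keep, , drop = FALSE]
}

#' Frame-selection configuration
#'
#' The minimum blob area is expressed physically (mm^2, default 0.2) so its
#' meaning survives resolution changes; it is converted through the pixel
#' scale at run time.
#'
#' @param window background window size in frames.
#' @param threshold foreground threshold in counts.
#' @param min_area_mm2 minimum blob area in mm^2.
#' @param min_bbox_side_px minimum blob bounding-box side in px.
#' @param connectivity 4 or 8.
#' @param scale a [px_scale()] or mm/px number.
#' @return a `selection_config` list.
#' @export
selection_config <- function(window = 50, threshold = 25, min_area_mm2 = 0.2,
                             min_bbox_side_px = 0, connectivity = 8,
                             scale = px_scale(0.0036)) {
  scale <- as_scale(scale)
  structure(list(window = window, threshold = threshold,
                 min_area_mm2 = min_area_mm2,
                 min_area_px = min_area_mm2 / scale$mm_per_px^2,
                 min_bbox_side_px = min_bbox_side_px,
                 connectivity = connectivity, scale = scale),
            class = "selection_config")
}

#' Select candidate frames from a stream
#'
#' Runs background subtraction, blob detection and size filtering on every
#' frame; a frame is selected iff at least one blob survives the filters.
#' All passing frames are selected (any further sub-sampling for annotation
#' is a downstream choice).
#'
#' @param stream a [frame_stream()].
#' @param config a [selection_config()].
#' @return a `candidate_frames` list: `manifest` (data.frame with
#'   `frame_index`, `n_blobs`, `max_blob_area_px`, `selected`), `blobs`
#'   (per-frame list of surviving blob tables), `config`.
#' @export
select_candidates <- function(stream, config = selection_config()) {
  stopifnot(inherits(stream, "frame_stream"))
  n <- stream$n
  w <- config$window
  if (n < w + 1L)
    stop(sprintf("stream of %d frames is shorter than window %d + target; use a smaller `window`",
                 n, w), call. = FALSE)
  h <- stream$height; wd <- stream$width
  npx <- h * wd
  # running sum over frames -> O(1) window means per frame
  flat <- stream$pixels
  dim(flat) <- c(npx, n)
  cs <- flat
  for (j in seq_len(n)[-1]) cs[, j] <- cs[, j - 1L] + flat[, j]
  manifest <- data.frame(frame_index = seq_len(n), n_blobs = 0L,
                         max_blob_area_px = 0L, selected = FALSE)
  blobs_by_frame <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- background_window_indices(n, i, w)
    lo <- min(idx); hi <- max(idx)
    tot <- cs[, hi] - (if (lo > 1L) cs[, lo - 1L] else 0)
    if (i >= lo && i <= hi) tot <- tot - flat[, i]
    mean_image <- matrix(tot / w, h, wd)
    fg <- abs(matrix(flat[, i], h, wd) - mean_image) > config$threshold
    bl <- filter_blobs(detect_blobs(fg, config$connectivity),
                       min_area = config$min_area_px,
                       min_bbox_side = config$min_bbox_side_px)
    blobs_by_frame[[i]] <- bl
    manifest$n_blobs[i] <- nrow(bl)
    manifest$max_blob_area_px[i] <- if (nrow(bl)) max(bl$area_px) else 0L
    manifest$selected[i] <- nrow(bl) > 0L
  }
  structure(list(manifest = manifest, blobs = blobs_by_frame, config = config),
            class = "candidate_frames")
}

#' @export
print.candidate_frames <- function(x, ...) {
  cat(sprintf("<candidate_frames> %d/%d frames selected\n",
              sum(x$manifest$selected), nrow(x$manifest)))
  invisible(x)
}

#' Write a selection manifest CSV
#'
#' @param candidates a [select_candidates()] result.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_selection_manifest <- function(candidates, path) {
  write.csv(candidates$manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
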