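#' Pixel scale
#'
#' The imaging system uses a telecentric lens, giving an orthographic view in
#' which object size in pixels is independent of distance. A single isotropic
#' scalar `mm_per_px` therefore converts pixel measurements to millimetres;
#' areas use `mm_per_px^2`, volumes are reported in mm^3.
#'
#' @param mm_per_px positive scalar, millimetres per pixel.
#' @return an object of class `px_scale`.
#' @examples
#' s <- px_scale(0.0036)
#' to_mm(100, s)
#' @export
px_scale <- function(mm_per_px) {
  if (!is.numeric(mm_per_px) || length(mm_per_px) != 1L ||
      !is.finite(mm_per_px) || mm_per_px <= 0) {
    stop("`mm_per_px` must be a single positive finite number", call. = FALSE)
  }
  structure(list(mm_per_px = as.numeric(mm_per_px)), class = "px_scale")
}

#' @export
print.px_scale <- function(x, ...) {
  cat(sprintf("<px_scale> %g mm/px\n", x$mm_per_px))
  invisible(x)
}

as_scale <- function(scale) {
  if (inherits(scale, "px_scale")) return(scale)
  px_scale(scale)
}

#' Convert pixel measurements to millimetres
#'
#' @param value_px length in pixels (vectorised).
#' @param scale a [px_scale()] or a bare positive mm/px number.
#' @return length in mm.
#' @export
to_mm <- function(value_px, scale) {
  scale <- as_scale(scale)
  value_px * scale$mm_per_px
}

#' @rdname to_mm
#' @param value_px2 area in square pixels.
#' @export
to_mm2 <- function(value_px2, scale) {
  scale <- as_scale(scale)
  value_px2 * scale$mm_per_px^2
}

#' Frame stream
#'
#' An ordered sequence of equally sized 8-bit grayscale frames, stored as a
#' `height x width x n` numeric array with values in `[0, 255]`. RGB input is
#' collapsed to luminance (equal-weight channel mean) on ingest: the analysis
#' is intensity-based.
#'
#' @param pixels a 3-D array `(h, w, n)`, or a list of `h x w` matrices.
#' @return an object of class `frame_stream`.
#' @export
frame_stream <- function(pixels) {
  if (is.list(pixels)) {
    dims <- unique(lapply(pixels, dim))
    if (length(dims) != 1L) stop("all frames must share height and width", call. = FALSE)
    pixels <- array(unlist(pixels, use.names = FALSE),
                    dim = c(dims[[1]], length(pixels)))
    dim(pixels) <- c(dims[[1]][1], dims[[1]][2], dim(pixels)[3])
  }
  if (length(dim(pixels)) == 2L) dim(pixels) <- c(dim(pixels), 1L)
  stopifnot(length(dim(pixels)) == 3L)
  structure(list(pixels = pixels,
                 height = dim(pixels)[1],
                 width  = dim(pixels)[2],
                 n      = dim(pixels)[3]),
            class = "frame_stream")
}

#' @export
print.frame_stream <- function(x, ...) {
  cat(sprintf("<frame_stream> %d frames of %d x %d px\n", x$n, x$height, x$width))
  invisible(x)
}

#' @rdname frame_stream
#' @param stream a `frame_stream`.
#' @param i frame index (1-based).
#' @return `get_frame()`: the `h x w` intensity matrix of frame `i`.
#' @export
get_frame <- function(stream, i) {
  stopifnot(inherits(stream, "frame_stream"), i >= 1L, i <= stream$n)
  stream$pixels[, , i]
}

#' Tight bounding box of a binary mask
#'
#' @param mask logical matrix.
#' @return `c(rmin, rmax, cmin, cmax)` (1-based, inclusive), or `NULL` for an
#'   empty mask.
#' @export
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  c(rmin = min(idx[, 1]), rmax = max(idx[, 1]),
    cmin = min(idx[, 2]), cmax = max(idx[, 2]))
}

#' Labelled image region
#'
#' The currency of the segmenter adapter: one binary mask tagged with a
#' feature class. Larva-mode classes are `body`, `eye`, `yolk`; egg-mode
#' classes are `egg`, `body`, `yolk`.
#'
#' @param feature_class one of `"body"`, `"eye"`, `"yolk"`, `"egg"`.
#' @param mask logical matrix, the full-frame binary mask.
#' @param confidence optional segmenter confidence in `[0, 1]`.
#' @return an object of class `labeled_region` with fields `feature_class`,
#'   `mask`, `area_px`, `bbox`, `confidence`.
#' @export
labeled_region <- function(feature_class, mask, confidence = NA_real_) {
  feature_class <- match.arg(feature_class, c("body", "eye", "yolk", "egg"))
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  structure(list(feature_class = feature_class,
                 mask = mask,
                 area_px = sum(mask),
                 bbox = mask_bbox(mask),
                 confidence = as.numeric(confidence)),
            class = "labeled_region")
}

#' @export
print.labeled_region <- function(x, ...) {
  cat(sprintf("<labeled_region> class=%s area=%d px conf=%s\n",
              x$feature_class, x$area_px,
              ifelse(is.na(x$confidence), "NA", format(x$confidence))))
  invisible(x)
}

region_centroid <- function(region) {
  idx <- which(region$mask, arr.ind = TRUE)
  c(row = mean(idx[, 1]), col = mean(idx[, 2]))
}

# Solidity = area / convex-hull area; used to flag two-lobed (figure-8)
# merged-eye regions. Hull from pixel centers, padded by the half-pixel the
# raster occupies beyond its centers.
region_solidity <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 3L) return(1)
  h <- grDevices::chull(idx[, 2], idx[, 1])
  hx <- idx[h, 2]; hy <- idx[h, 1]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  # hull of pixel centers underestimates raster extent by ~ perimeter/2
  per <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
  hull_area <- hull_area + per / 2 + 1
  min(1, n / hull_area)
}

#' Read image frames from files
#'
#' Loads numerically ordered PNG (or TIFF, if the `tiff` package is
#' installed) frames into a [frame_stream()]. RGB images are collapsed to
#' luminance. Intensities are rescaled to 0-255 counts.
#'
#' @param paths character vector of image files, or a single directory whose
#'   `.png`/`.tif(f)` files are taken in lexicographic order.
#' @return a [frame_stream()].
#' @export
read_frames <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    paths <- sort(paths)
  }
  if (length(paths) == 0L) stop("no image files found", call. = FALSE)
  frames <- lapply(paths, read_one_image)
  frame_stream(frames)
}

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3L) img <- rowMeans(img, dims = 2L)  # luminance
  img * 255
}

#' Write a frame stream as numbered PNG files
#'
#' @param stream a [frame_stream()].
#' @param dir output directory (created if absent).
#' @param prefix filename prefix.
#' @return invisibly, the written paths.
#' @export
write_frames <- function(stream, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(stream$n)
  for (i in seq_len(stream$n)) {
    paths[i] <- file.path(dir, sprintf("%s_%05d.png", prefix, i))
    png::writePNG(pmin(pmax(get_frame(stream, i), 0), 255) / 255, paths[i])
  }
  invisible(paths)
}
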