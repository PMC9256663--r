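# Annotation data model: hand-drawn feature outlines are smoothed, resampled
# as evenly spaced polygon vertices, stored as CSV (coordinates) and 8-bit
# PNG (label masks), and split into training/validation sets.

#' Feature outline
#'
#' A closed polygon (first vertex not repeated) outlining one feature
#' instance. Vertices are `(row, col)` pixel coordinates; sub-pixel values
#' are allowed.
#'
#' @param feature_class one of `"body"`, `"eye"`, `"yolk"`, `"egg"`.
#' @param points numeric matrix with columns `row`, `col`, >= 3 rows.
#' @param source_image optional image identifier.
#' @return an `outline` object; `$simple` is `FALSE` when the polygon
#'   self-intersects.
#' @export
outline <- function(feature_class, points, source_image = NA_character_) {
  feature_class <- match.arg(feature_class, c("body", "eye", "yolk", "egg"))
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("an outline needs at least 3 points", call. = FALSE)
  colnames(points) <- c("row", "col")
  structure(list(feature_class = feature_class, points = points,
                 source_image = source_image,
                 simple = is_simple_polygon(points)),
            class = "outline")
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf("<outline> class=%s %d vertices%s\n", x$feature_class,
              nrow(x$points), if (!x$simple) " (self-intersecting)" else ""))
  invisible(x)
}

# O(n^2) segment-intersection check; n is ~100 after resampling.
is_simple_polygon <- function(pts) {
  n <- nrow(pts)
  if (n < 4L) return(TRUE)
  p <- rbind(pts, pts[1L, ])
  seg_int <- function(a1, a2, b1, b2) {
    d1 <- cross2(b2 - b1, a1 - b1); d2 <- cross2(b2 - b1, a2 - b1)
    d3 <- cross2(a2 - a1, b1 - a1); d4 <- cross2(a2 - a1, b2 - a1)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    js <- seq.int(i + 2L, jmax)
    for (j in js) {
      if (seg_int(p[i, ], p[i + 1L, ], p[j, ], p[j + 1L, ])) return(FALSE)
    }
  }
  TRUE
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

#' Smooth an outline by circular moving average
#'
#' Each vertex is replaced by the mean of a window of `smoothing_window`
#' consecutive vertices centred on it, wrapping around the closed polygon.
#' Vertex count is unchanged and the vertex centroid is preserved exactly
#' (a mean filter preserves the mean).
#'
#' @param points vertex matrix (or an [outline()]).
#' @param smoothing_window odd window size in vertices; 1 is the identity.
#' @return smoothed vertex matrix (or outline).
#' @export
smooth_outline <- function(points, smoothing_window = 5) {
  if (inherits(points, "outline")) {
    out <- points
    out$points <- smooth_outline(points$points, smoothing_window)
    out$simple <- is_simple_polygon(out$points)
    return(out)
  }
  pts <- as.matrix(points)
  if (nrow(pts) < 3L) stop("an outline needs at least 3 points", call. = FALSE)
  w <- as.integer(smoothing_window)
  if (w < 1L || w %% 2L == 0L) stop("`smoothing_window` must be odd and >= 1", call. = FALSE)
  if (w == 1L) return(pts)
  n <- nrow(pts)
  half <- (w - 1L) %/% 2L
  out <- pts * 0
  for (d in seq.int(-half, half)) {
    sh <- ((seq_len(n) - 1L + d) %% n) + 1L
    out <- out + pts[sh, , drop = FALSE]
  }
  out / w
}

#' Resample an outline at evenly spaced arc lengths
#'
#' Places `n_points` vertices on the closed polyline at equal arc-length
#' spacing (`perimeter / n_points`), anchored at the first input vertex.
#'
#' @param points vertex matrix (or an [outline()]).
#' @param n_points number of output vertices, >= 3.
#' @return resampled vertex matrix (or outline).
#' @export
resample_evenly <- function(points, n_points = 100) {
  if (inherits(points, "outline")) {
    out <- points
    out$points <- resample_evenly(points$points, n_points)
    out$simple <- is_simple_polygon(out$points)
    return(out)
  }
  pts <- as.matrix(points)
  n_points <- as.integer(n_points)
  if (n_points < 3L) stop("`n_points` must be >= 3", call. = FALSE)
  closed <- rbind(pts, pts[1L, , drop = FALSE])
  seg <- sqrt(rowSums(diff(closed)^2))
  per <- sum(seg)
  if (per <= 0) stop("outline has zero perimeter", call. = FALSE)
  cum <- c(0, cumsum(seg))
  targets <- (seq_len(n_points) - 1L) * per / n_points
  ii <- findInterval(targets, cum, rightmost.closed = TRUE)
  ii <- pmin(ii, length(seg))
  frac <- (targets - cum[ii]) / pmax(seg[ii], .Machine$double.eps)
  out <- closed[ii, , drop = FALSE] +
    (closed[ii + 1L, , drop = FALSE] - closed[ii, , drop = FALSE]) * frac
  colnames(out) <- c("row", "col")
  out
}

#' Rasterize an outline to a binary mask
#'
#' Scanline even-odd fill over pixel centers, plus the outline's own boundary
#' pixels, so a square outline through pixel centers `(1,1)..(20,20)` fills
#' exactly 400 pixels. Vertices outside the image are clipped with a warning.
#'
#' @param outline an [outline()] or a vertex matrix.
#' @param image_shape `c(height, width)`.
#' @return logical matrix.
#' @export
outline_to_mask <- function(outline, image_shape) {
  pts <- if (inherits(outline, "outline")) outline$points else as.matrix(outline)
  h <- image_shape[1]; w <- image_shape[2]
  if (any(pts[, 1] < 1 | pts[, 1] > h | pts[, 2] < 1 | pts[, 2] > w)) {
    warning("outline extends beyond the image; mask is clipped", call. = FALSE)
  }
  mask <- matrix(FALSE, h, w)
  closed <- rbind(pts, pts[1L, , drop = FALSE])
  y1 <- closed[-nrow(closed), 1]; x1 <- closed[-nrow(closed), 2]
  y2 <- closed[-1L, 1];           x2 <- closed[-1L, 2]
  for (r in max(1L, ceiling(min(pts[, 1]))):min(h, floor(max(pts[, 1])))) {
    sp <- (pmin(y1, y2) <= r) & (r < pmax(y1, y2))   # half-open in y
    if (!any(sp)) next
    xi <- x1[sp] + (r - y1[sp]) * (x2[sp] - x1[sp]) / (y2[sp] - y1[sp])
    xi <- sort(xi)
    for (k in seq(1L, length(xi) - 1L, by = 2L)) {
      a <- ceiling(xi[k] - 1e-9); b <- floor(xi[k + 1L] + 1e-9)
      a <- max(1L, a); b <- min(w, b)
      if (a <= b) mask[r, a:b] <- TRUE
    }
  }
  # include the outline trace itself
  for (i in seq_len(nrow(closed) - 1L)) {
    p <- closed[i, ]; q <- closed[i + 1L, ]
    steps <- max(2L, ceiling(2 * sqrt(sum((q - p)^2))))
    t <- seq(0, 1, length.out = steps)
    rr <- round(p[1] + t * (q[1] - p[1])); cc <- round(p[2] + t * (q[2] - p[2]))
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  mask
}

#' Trace the outline of a binary mask
#'
#' Boundary tracing of the largest connected component.
#'
#' @param mask logical matrix, non-empty.
#' @param feature_class class label attached to the traced outline.
#' @return an [outline()].
#' @export
mask_to_outline <- function(mask, feature_class = "body") {
  if (!any(mask)) stop("cannot trace an empty mask", call. = FALSE)
  lab <- label_components(mask, 8)
  big <- which.max(tabulate(lab[lab > 0L]))
  cont <- EBImage::ocontour(EBImage::Image((lab == big) * 1))
  pts <- cont[[which.max(vapply(cont, nrow, integer(1)))]] + 1  # 0- to 1-based
  outline(feature_class, pts[, c(1, 2), drop = FALSE])
}

#' Split annotation ids into training and validation sets
#'
#' Deterministic given `seed`; each id is assigned exactly once and the
#' training count is `round(train_fraction * n)` (within one item of the
#' configured fraction, default 0.9/0.1).
#'
#' @param ids character or integer vector of annotation/image ids.
#' @param train_fraction in (0, 1).
#' @param seed integer RNG seed.
#' @return data.frame with columns `id`, `split` (`"train"`/`"validation"`),
#'   `seed`.
#' @export
split_dataset <- function(ids, train_fraction = 0.9, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  n <- length(ids)
  if (n == 0L) return(data.frame(id = character(), split = character(),
                                 seed = integer()))
  n_train <- round(train_fraction * n)
  perm <- with_preserved_seed(seed, sample.int(n))
  split <- rep("validation", n)
  split[perm[seq_len(n_train)]] <- "train"
  data.frame(id = ids, split = split, seed = as.integer(seed))
}

# Run `expr` under `set.seed(seed)` without disturbing the caller's RNG.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write / read polygon annotation CSVs
#'
#' One row per vertex with columns `image_id, feature_class, instance_index,
#' point_index, row, col`. Coordinates are serialized with 17 significant
#' digits so a write/read round trip is bit-exact.
#'
#' @param outlines list of [outline()] objects.
#' @param path CSV path.
#' @param image_id image identifier recorded in the file.
#' @return `write_annotation_csv()`: invisibly, `path`;
#'   `read_annotation_csv()`: a list of outlines.
#' @export
write_annotation_csv <- function(outlines, path, image_id = "image") {
  rows <- lapply(seq_along(outlines), function(i) {
    o <- outlines[[i]]
    data.frame(image_id = if (!is.na(o$source_image)) o$source_image else image_id,
               feature_class = o$feature_class,
               instance_index = i,
               point_index = seq_len(nrow(o$points)),
               row = sprintf("%.17g", o$points[, 1]),
               col = sprintf("%.17g", o$points[, 2]))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotation_csv
#' @export
read_annotation_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$instance_index), function(d) {
    d <- d[order(d$point_index), ]
    outline(d$feature_class[1],
            cbind(row = as.numeric(d$row), col = as.numeric(d$col)),
            source_image = d$image_id[1])
  })
}

#' Write / read instance label masks as lossless 8-bit PNG
#'
#' One file per image per class: background 0, instances encoded as gray
#' levels `1..n`.
#'
#' @param masks list of logical matrices (instances of one class).
#' @param path PNG path.
#' @return `write_label_png()`: invisibly, `path`; `read_label_png()`: a list
#'   of logical instance masks.
#' @export
write_label_png <- function(masks, path) {
  stopifnot(length(masks) >= 1L, length(masks) <= 255L)
  lab <- matrix(0L, nrow(masks[[1]]), ncol(masks[[1]]))
  for (i in seq_along(masks)) lab[masks[[i]] != 0] <- i
  png::writePNG(lab / 255, path)
  invisible(path)
}

#' @rdname write_label_png
#' @export
read_label_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  lab <- round(img * 255)
  lapply(seq_len(max(lab)), function(i) lab == i)
}
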