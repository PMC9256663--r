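# Skeleton centerline extraction. The body mask is thinned to a
# one-pixel-wide skeleton, boundary-artifact spurs are pruned (a spur's
# length is comparable to the local inscribed radius, a genuine tail is much
# longer), the longest end-to-end path is taken as the centerline trunk, and
# both endpoints are extended to the mask boundary along the terminal
# tangent so the measured length spans snout to tail tip.

#' Morphological skeleton of a binary mask
#'
#' @param mask logical matrix.
#' @return logical matrix of the same shape containing the thinned skeleton.
#' @export
skeletonize <- function(mask) {
  bb <- mask_bbox(mask)
  if (is.null(bb)) return(mask & FALSE)
  sub <- mask[bb["rmin"]:bb["rmax"], bb["cmin"]:bb["cmax"], drop = FALSE]
  thin <- .thin_zhangsuen(matrix(as.integer(sub), nrow(sub), ncol(sub)))
  out <- mask & FALSE
  out[bb["rmin"]:bb["rmax"], bb["cmin"]:bb["cmax"]] <- thin != 0
  out
}

# 8-neighbour adjacency of skeleton pixels: vertices = pixel coords,
# edges weighted 1 (orthogonal) / sqrt(2) (diagonal). A diagonal edge is
# added only when neither of its two bridging orthogonal pixels is on the
# skeleton; otherwise staircase corners would form 3-cycles that read as
# spurious junctions.
skeleton_adjacency <- function(coords, nr) {
  n <- nrow(coords)
  key <- coords[, 1] + (coords[, 2] - 1) * nr
  lookup <- function(r, c) {
    k <- r + (c - 1) * nr
    j <- match(k, key)
    j[r < 1 | r > nr] <- NA_integer_
    j
  }
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  from <- integer(); to <- integer(); w <- numeric()
  for (k in seq_len(8)) {
    dr <- offs[k, 1]; dc <- offs[k, 2]
    j <- lookup(coords[, 1] + dr, coords[, 2] + dc)
    keep <- !is.na(j)
    if (dr != 0 && dc != 0) {
      # drop staircase-corner diagonals bridged by an orthogonal pixel
      b1 <- lookup(coords[, 1] + dr, coords[, 2])
      b2 <- lookup(coords[, 1], coords[, 2] + dc)
      keep <- keep & is.na(b1) & is.na(b2)
    }
    from <- c(from, which(keep))
    to <- c(to, j[keep])
    w <- c(w, rep.int(if (dr != 0 && dc != 0) sqrt(2) else 1, sum(keep)))
  }
  adj <- rep(list(integer()), n)
  wts <- rep(list(numeric()), n)
  sp <- split(seq_along(from), from)
  for (nm in names(sp)) {
    i <- as.integer(nm)
    adj[[i]] <- to[sp[[nm]]]
    wts[[i]] <- w[sp[[nm]]]
  }
  list(adj = adj, wts = wts)
}

# Remove endpoint branches shorter than ~ the local inscribed radius at
# their junction; these are thinning artifacts at wide blunt ends.
prune_spurs <- function(coords, adjw, dist_at, nr) {
  repeat {
    deg <- lengths(adjw$adj)
    ends <- which(deg == 1L)
    if (length(ends) == 0L) return(list(coords = coords, adjw = adjw))
    drop <- rep(FALSE, nrow(coords))
    any_pruned <- FALSE
    for (e in ends) {
      path <- e; len <- 0; prev <- 0L; cur <- e
      repeat {
        nbs <- adjw$adj[[cur]]; ws <- adjw$wts[[cur]]
        sel <- nbs != prev
        if (!any(sel)) { junction <- NA_integer_; break }  # isolated path
        if (sum(sel) > 1L) { junction <- cur; path <- path[-length(path)]; break }
        nxt <- nbs[sel][1L]; w <- ws[sel][1L]
        if (length(adjw$adj[[nxt]]) >= 3L) { junction <- nxt; len <- len + w; break }
        path <- c(path, nxt); len <- len + w
        prev <- cur; cur <- nxt
        if (length(path) > nrow(coords)) { junction <- NA_integer_; break }
      }
      if (!is.na(junction) && length(path) > 0L &&
          len <= 1.5 * dist_at[junction] + 2) {
        drop[path] <- TRUE
        any_pruned <- TRUE
      }
    }
    if (!any_pruned) return(list(coords = coords, adjw = adjw))
    keep <- which(!drop)
    dist_at <- dist_at[keep]
    coords <- coords[keep, , drop = FALSE]
    adjw <- skeleton_adjacency(coords, nr)
  }
}

#' Extract the centerline of a body mask
#'
#' Thins the mask to a skeleton, prunes spurs, takes the longest end-to-end
#' path, and extends both endpoints to the mask boundary along the terminal
#' tangent. Arc length accumulates 1 per orthogonal and `sqrt(2)` per
#' diagonal step, plus the endpoint extensions.
#'
#' @param body_mask logical matrix: a single connected, hole-free region.
#' @return a `centerline` object: `points` (ordered `(row, col)` polyline,
#'   sub-pixel endpoints), `arc_length_px`, `flags` (may contain
#'   `"low_elongation"` or `"loop"`).
#' @export
extract_centerline <- function(body_mask) {
  if (!any(body_mask)) stop("empty body mask", call. = FALSE)
  lab <- label_components(body_mask, 8)
  if (max(lab) > 1L) stop("body mask is disconnected", call. = FALSE)
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(body_mask * 1)))
  skel <- skeletonize(body_mask)
  coords <- which(skel, arr.ind = TRUE)
  flags <- character()
  if (nrow(coords) < 3L) {
    return(degenerate_centerline(body_mask, dm))
  }
  nr <- nrow(body_mask)
  adjw <- skeleton_adjacency(coords, nr)
  pr <- prune_spurs(coords, adjw, dm[coords], nr)
  coords <- pr$coords; adjw <- pr$adjw
  if (nrow(coords) < 3L) return(degenerate_centerline(body_mask, dm))
  # longest endpoint-to-endpoint path on the pruned skeleton
  el <- edge_list(adjw)
  g <- igraph::graph_from_data_frame(
    data.frame(from = el$from, to = el$to), directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(coords))))
  igraph::E(g)$weight <- el$w
  deg <- igraph::degree(g)
  ends <- which(deg <= 1L)
  if (length(ends) < 2L) {
    flags <- c(flags, "loop")
    d0 <- igraph::distances(g, v = 1)
    a <- which.max(d0)
    da <- igraph::distances(g, v = a)
    # break the cycle: path to the farthest vertex
    ends <- c(a, which.max(da))
  }
  dmat <- igraph::distances(g, v = ends, to = ends)
  best <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
  vpath <- igraph::shortest_paths(g, from = ends[best[1]],
                                  to = ends[best[2]])$vpath[[1]]
  path_idx <- as.integer(igraph::as_ids(vpath))
  pts <- smooth_path(coords[path_idx, , drop = FALSE])
  arc <- sum(sqrt(rowSums(diff(pts)^2)))
  # extend both ends to the boundary along the terminal tangent
  ext1 <- extend_to_boundary(pts, body_mask, end = "first")
  ext2 <- extend_to_boundary(pts, body_mask, end = "last")
  pts <- rbind(ext1$point, pts, ext2$point)
  arc <- arc + ext1$length + ext2$length
  if (arc < 3 * max(dm)) flags <- c(flags, "low_elongation")
  structure(list(points = pts, arc_length_px = arc, flags = flags),
            class = "centerline")
}

# Moving-average smoothing of an open polyline (shrinking window at the
# ends, endpoints fixed). Removes the staircase jitter of a digital path,
# which otherwise overestimates the arc length of curved bodies by a few
# percent; the window is far shorter than any body curvature radius of
# interest, so genuine curvature is preserved.
smooth_path <- function(pts, window = 7L) {
  n <- nrow(pts)
  if (n <= window) return(pts)
  half <- window %/% 2L
  out <- pts
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    if (h > 0L) out[i, ] <- colMeans(pts[(i - h):(i + h), , drop = FALSE])
  }
  out
}

edge_list <- function(adjw) {
  from <- integer(); to <- integer(); w <- numeric()
  for (i in seq_along(adjw$adj)) {
    nbs <- adjw$adj[[i]]
    sel <- nbs > i
    from <- c(from, rep.int(i, sum(sel)))
    to <- c(to, nbs[sel])
    w <- c(w, adjw$wts[[i]][sel])
  }
  list(from = from, to = to, w = w)
}

# Degenerate (disc-like) mask: centerline along the second-moment major axis
# through the centroid, cut to the mask.
degenerate_centerline <- function(mask, dm) {
  idx <- which(mask, arr.ind = TRUE)
  cen <- colMeans(idx)
  ax <- measure_axes(mask)
  dir <- c(sin(ax$orientation_rad), cos(ax$orientation_rad))  # (drow, dcol)
  a <- march_out(cen, dir, mask)
  b <- march_out(cen, -dir, mask)
  pts <- rbind(b, cen, a)
  structure(list(points = pts,
                 arc_length_px = sqrt(sum((a - b)^2)),
                 flags = "low_elongation"),
            class = "centerline")
}

march_out <- function(start, dir, mask, step = 0.25) {
  nr <- nrow(mask); nc <- ncol(mask)
  t <- 0
  repeat {
    tn <- t + step
    p <- start + tn * dir
    rp <- round(p[1]); cp <- round(p[2])
    if (rp < 1 || cp < 1 || rp > nr || cp > nc || !mask[rp, cp]) break
    t <- tn
    if (t > nr + nc) break
  }
  start + t * dir
}

extend_to_boundary <- function(pts, mask, end = c("first", "last")) {
  end <- match.arg(end)
  n <- nrow(pts)
  k <- min(10L, n - 1L)
  if (end == "first") { p0 <- pts[1L, ]; pin <- pts[1L + k, ] }
  else { p0 <- pts[n, ]; pin <- pts[n - k, ] }
  dir <- p0 - pin
  nrm <- sqrt(sum(dir^2))
  if (nrm < .Machine$double.eps) return(list(point = p0, length = 0))
  dir <- dir / nrm
  p <- march_out(p0, dir, mask)
  list(point = p, length = sqrt(sum((p - p0)^2)))
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, arc length %.1f px%s\n",
              nrow(x$points), x$arc_length_px,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

# Body-curvature statistic: the spread (max - min) of the unwrapped tangent
# heading along the centerline, sampled at ~5 px arc spacing. A straight
# body scores ~0, a semicircular pose exactly pi, a curled (over-bent) pose
# beyond pi. The spread is robust to pixel-level heading jitter, which
# cancels instead of accumulating as it would in a total-variation sum.
centerline_turning_angle <- function(centerline, spacing = 5) {
  pts <- centerline$points
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  if (L <= 2 * spacing) return(0)
  targets <- seq(0, L, by = spacing)
  ii <- findInterval(targets, cum, rightmost.closed = TRUE)
  ii <- pmin(ii, length(seg))
  frac <- (targets - cum[ii]) / pmax(seg[ii], .Machine$double.eps)
  rs <- pts[ii, , drop = FALSE] + (pts[ii + 1L, , drop = FALSE] - pts[ii, , drop = FALSE]) * frac
  hd <- atan2(diff(rs[, 1]), diff(rs[, 2]))
  dh <- diff(hd)
  dh <- (dh + pi) %% (2 * pi) - pi
  unwrapped <- cumsum(c(hd[1], dh))
  diff(range(unwrapped))
}
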