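# Shared fixtures and independent oracles, all built in code.

# independent disc rasterizer (pixel-centre inclusion)
disc_mask <- function(shape, r0, c0, radius) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (r in seq_len(shape[1])) {
    for (cc in seq_len(shape[2])) {
      if ((r - r0)^2 + (cc - c0)^2 <= radius^2) m[r, cc] <- TRUE
    }
  }
  m
}

# independent rotated-ellipse rasterizer (vectorised but written from the
# quadratic form directly, not via the package's internals)
ellipse_mask <- function(shape, r0, c0, a_semi, b_semi, angle = 0) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  u <- (cols - c0) * cos(angle) + (rows - r0) * sin(angle)
  v <- -(cols - c0) * sin(angle) + (rows - r0) * cos(angle)
  (u / a_semi)^2 + (v / b_semi)^2 <= 1
}

rect_mask <- function(shape, r1, r2, c1, c2) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[r1:r2, c1:c2] <- TRUE
  m
}

# flat-ended semicircular tube: the polar band |rho - R| <= halfwidth over
# the upper half-plane of `center` (independent of the package's renderer)
arc_tube_mask <- function(shape, center, radius, halfwidth) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  rho <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  abs(rho - radius) <= halfwidth & rows <= center[1]
}

region_of <- function(class, mask, conf = NA_real_) {
  labeled_region(class, mask, confidence = conf)
}

# ---- brute-force frame-selection oracle (explicit loops) ----------------

naive_window_indices <- function(n, index, window) {
  others <- setdiff(seq_len(n), index)
  d <- abs(others - index)
  others[order(d, others)][seq_len(window)]
}

naive_background <- function(stream, index, window) {
  idx <- sort(naive_window_indices(stream$n, index, window))
  acc <- matrix(0, stream$height, stream$width)
  for (i in idx) acc <- acc + stream$pixels[, , i]
  acc / window
}

naive_foreground <- function(frame, bg, threshold) {
  out <- matrix(FALSE, nrow(frame), ncol(frame))
  for (r in seq_len(nrow(frame))) {
    for (cc in seq_len(ncol(frame))) {
      out[r, cc] <- abs(frame[r, cc] - bg[r, cc]) > threshold
    }
  }
  out
}

# flood-fill connected-component labelling with explicit queues
naive_label <- function(mask, connectivity = 8) {
  offs <- if (connectivity == 8)
    rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else rbind(c(-1,0), c(0,-1), c(0,1), c(1,0))
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pr <- (p - 1L) %% nrow(mask) + 1L
      pc <- (p - 1L) %/% nrow(mask) + 1L
      for (k in seq_len(nrow(offs))) {
        r <- pr + offs[k, 1]; cc <- pc + offs[k, 2]
        if (r < 1 || cc < 1 || r > nrow(mask) || cc > ncol(mask)) next
        q <- (cc - 1L) * nrow(mask) + r
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# canonical form of a blob table for set comparison
blob_signature <- function(blobs) {
  if (nrow(blobs) == 0L) return(character())
  sort(sprintf("%d:%d-%d:%d-%d", blobs$area_px, blobs$rmin, blobs$rmax,
               blobs$cmin, blobs$cmax))
}

# regular polygon helper
regular_polygon <- function(n, radius = 10, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(row = center[1] + radius * sin(th), col = center[2] + radius * cos(th))
}

# ---- voxel-count volume oracles ----------------------------------------

voxel_cylinder_volume <- function(diameter, length, pitch) {
  g <- seq(-diameter / 2, diameter / 2, by = pitch)
  inside <- outer(g^2, g^2, "+") <= (diameter / 2)^2
  n_slices <- floor(length / pitch)
  sum(inside) * n_slices * pitch^3
}

voxel_spheroid_volume <- function(W, L, pitch) {
  gx <- seq(-W / 2, W / 2, by = pitch)
  gz <- seq(-L / 2, L / 2, by = pitch)
  xy2 <- outer(gx^2, gx^2, "+") / (W / 2)^2
  total <- 0
  for (z in gz) total <- total + sum(xy2 + z^2 / (L / 2)^2 <= 1)
  total * pitch^3
}

voxel_sphere_volume <- function(D, pitch) voxel_spheroid_volume(D, D, pitch)
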