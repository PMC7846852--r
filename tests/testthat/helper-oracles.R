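# Independent oracles and small generators shared across the suite.

# Brute-force oracle for supercover traversal: for EVERY pixel in the
# segments' bounding box, clip the segment to the pixel's closed square
# (Liang-Barsky slab intersection) and accept the pixel iff the clipped
# piece has positive length and its midpoint lies strictly inside the open
# square (which rejects corner touches and runs along shared edges). A
# dense point-sampling pass (pixels containing an interior sample point)
# must be a subset; tiny corner-clipping chords can evade uniform sampling,
# which is why the exhaustive clip is the oracle of record.
oracle_trace <- function(vertices, grid_dim, n_per_segment = 10000L) {
  hit <- matrix(FALSE, grid_dim[1], grid_dim[2])
  for (i in seq_len(nrow(vertices) - 1L)) {
    p0 <- vertices[i, ]; p1 <- vertices[i + 1L, ]
    d <- p1 - p0
    r_rng <- max(0L, floor(min(p0[1], p1[1]))):min(grid_dim[1] - 1L,
                                                   floor(max(p0[1], p1[1])))
    c_rng <- max(0L, floor(min(p0[2], p1[2]))):min(grid_dim[2] - 1L,
                                                   floor(max(p0[2], p1[2])))
    for (r in r_rng) for (cc in c_rng) {
      t0 <- 0; t1 <- 1; ok <- TRUE
      for (k in 1:2) {
        lo <- if (k == 1) r else cc
        if (d[k] == 0) {
          if (p0[k] < lo || p0[k] > lo + 1) { ok <- FALSE; break }
        } else {
          ta <- (lo - p0[k]) / d[k]; tb <- (lo + 1 - p0[k]) / d[k]
          t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
          if (t0 >= t1) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      mid <- p0 + (t0 + t1) / 2 * d
      if (mid[1] > r && mid[1] < r + 1 && mid[2] > cc && mid[2] < cc + 1)
        hit[r + 1L, cc + 1L] <- TRUE
    }
    # sampled interior points must land only on accepted pixels
    t <- seq(0, 1, length.out = n_per_segment)
    pr <- p0[1] + t * d[1]; pc <- p0[2] + t * d[2]
    keep <- pr != floor(pr) & pc != floor(pc) &
      pr >= 0 & pr < grid_dim[1] & pc >= 0 & pc < grid_dim[2]
    stopifnot(all(hit[cbind(floor(pr[keep]) + 1, floor(pc[keep]) + 1)]))
  }
  idx <- which(hit, arr.ind = TRUE) - 1L
  pix <- cbind(idx[, 1], idx[, 2])
  pix[order(pix[, 1], pix[, 2]), , drop = FALSE]
}

pixel_set_sorted <- function(pix) {
  pix <- unname(as.matrix(pix))
  pix[order(pix[, 1], pix[, 2]), , drop = FALSE]
}

# point-in-polygon oracle on pixel centers (mgcv's independent routine)
oracle_rasterize <- function(vertices, grid_dim) {
  bnd <- rbind(vertices, vertices[1, ])
  cand <- expand.grid(row = 0:(grid_dim[1] - 1L), col = 0:(grid_dim[2] - 1L))
  # mgcv::in.out takes (x, y); feed (col, row) consistently for both
  inside <- mgcv::in.out(cbind(bnd[, 2], bnd[, 1]),
                         cbind(cand$col + 0.5, cand$row + 0.5))
  pixel_set_sorted(cbind(cand$row[inside], cand$col[inside]))
}

# random geometry generators (continuous coordinates, off-grid-line)
random_polyline <- function(n_vertices, grid_dim, seed) {
  set.seed(seed)
  repeat {
    v <- cbind(runif(n_vertices, 1, grid_dim[1] - 1),
               runif(n_vertices, 1, grid_dim[2] - 1))
    if (all(rowSums(abs(diff(v))) > 0)) return(v)
  }
}

random_polygon <- function(n_vertices, grid_dim, seed) {
  set.seed(seed)
  # star-shaped around a random center: sorted angles avoid degenerate
  # self-intersections while still exercising concavity
  ctr <- c(runif(1, grid_dim[1] * 0.3, grid_dim[1] * 0.7),
           runif(1, grid_dim[2] * 0.3, grid_dim[2] * 0.7))
  th <- sort(runif(n_vertices, 0, 2 * pi))
  rad <- runif(n_vertices, 2, min(grid_dim) * 0.4)
  cbind(ctr[1] + rad * sin(th), ctr[2] + rad * cos(th))
}

# small helper: map filled with a constant
const_map <- function(value, n = 16, spacing = c(1, 1), phase = "native") {
  t1_map(matrix(value, n, n), pixel_spacing = spacing, phase = phase)
}
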