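# Pixel-set extraction from operator geometry.
#
# Both routines share the package coordinate convention: pixel (r, c) is
# the half-open square [r, r+1) x [c, c+1), zero-based.

#' Pixels crossed by a polyline (supercover traversal)
#'
#' Returns exactly the pixels whose interior (open square) is intersected
#' by the polyline, each listed once in first-crossing order. Pixels the
#' line touches only at a corner, or only along a shared edge boundary, are
#' excluded: the crossing must have positive length inside the open square.
#' This is the sampling rule of the centerline "line of interest" method —
#' the traversed pixels' T1 values are averaged without contouring the
#' wall.
#'
#' @param loi a [polyline_loi] in continuous pixel coordinates.
#' @param grid_dim (rows, cols) of the target map; crossings outside the
#'   grid are dropped.
#' @return integer matrix with columns \code{row}, \code{col} (zero-based).
#' @export
trace_loi_pixels <- function(loi, grid_dim) {
  stopifnot(inherits(loi, "polyline_loi"), length(grid_dim) == 2L)
  v <- loi$vertices
  pix <- matrix(integer(0), ncol = 2L)
  for (i in seq_len(nrow(v) - 1L))
    pix <- rbind(pix, .trace_segment(v[i, ], v[i + 1L, ]))
  keep <- pix[, 1] >= 0L & pix[, 1] < grid_dim[1] &
          pix[, 2] >= 0L & pix[, 2] < grid_dim[2]
  pix <- pix[keep, , drop = FALSE]
  pix <- pix[!duplicated(pix), , drop = FALSE]
  if (nrow(pix) == 0L)
    stop("polyline crosses no pixel interior inside the grid")
  colnames(pix) <- c("row", "col")
  pix
}

# Pixels whose open interior is crossed by segment p0 -> p1, in order.
# Splits [0,1] at every grid-line crossing and classifies each sub-interval
# by its midpoint; a midpoint sitting exactly on a grid line means the
# sub-segment runs along a pixel boundary and samples no interior.
.trace_segment <- function(p0, p1) {
  d <- p1 - p0
  ts <- c(0, 1)
  for (k in 1:2) {
    if (d[k] != 0) {
      lo <- min(p0[k], p1[k]); hi <- max(p0[k], p1[k])
      lines <- seq.int(ceiling(lo), floor(hi))
      lines <- lines[lines > lo & lines < hi]
      if (length(lines)) ts <- c(ts, (lines - p0[k]) / d[k])
    }
  }
  ts <- sort(unique(ts))
  mids <- (ts[-length(ts)] + ts[-1]) / 2
  pr <- p0[1] + mids * d[1]
  pc <- p0[2] + mids * d[2]
  # a midpoint sitting exactly on a grid line marks a sub-segment running
  # along a pixel boundary (or a degenerate graze): no interior sampled
  keep <- (pr != floor(pr)) & (pc != floor(pc))
  cbind(row = as.integer(floor(pr[keep])), col = as.integer(floor(pc[keep])))
}

#' Rasterize a polygon ROI to the pixels whose centers it contains
#'
#' Uses the even-odd rule on pixel centers \code{(r + 0.5, c + 0.5)}. A
#' center lying exactly on a polygon edge is resolved by the top-left rule:
#' the test point is nudged by +2^-32 in both row and col, so edges along
#' the top or left of the enclosed region claim the center.
#'
#' @param roi a [polygon_roi].
#' @param grid_dim (rows, cols) of the target map.
#' @return integer matrix with columns \code{row}, \code{col} (zero-based).
#' @export
rasterize_polygon <- function(roi, grid_dim) {
  stopifnot(inherits(roi, "polygon_roi"), length(grid_dim) == 2L)
  v <- roi$vertices
  r0 <- max(0L, floor(min(v[, 1])))
  r1 <- min(grid_dim[1] - 1L, ceiling(max(v[, 1])))
  c0 <- max(0L, floor(min(v[, 2])))
  c1 <- min(grid_dim[2] - 1L, ceiling(max(v[, 2])))
  if (r1 < r0 || c1 < c0) stop("polygon encloses no pixel center inside the grid")
  cand <- expand.grid(row = r0:r1, col = c0:c1)
  eps <- 2^-32
  inside <- .point_in_polygon_eo(cand$row + 0.5 + eps, cand$col + 0.5 + eps, v)
  if (!any(inside)) stop("polygon encloses no pixel center inside the grid")
  m <- cbind(row = cand$row[inside], col = cand$col[inside])
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# vectorized even-odd crossing test; ray cast in +col direction
.point_in_polygon_eo <- function(pr, pc, v) {
  n <- nrow(v)
  inside <- logical(length(pr))
  j <- n
  for (i in seq_len(n)) {
    ri <- v[i, 1]; ci <- v[i, 2]; rj <- v[j, 1]; cj <- v[j, 2]
    crosses <- ((ri > pr) != (rj > pr)) &
      (pc < (cj - ci) * (pr - ri) / (rj - ri) + ci)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
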