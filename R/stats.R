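#' T1 statistics over a sampled pixel set
#'
#' `loi_stats()` samples the pixels crossed by a centerline polyline
#' ([trace_loi_pixels]); `roi_stats()` samples the pixels whose centers lie
#' inside a planimetric contour ([rasterize_polygon]). Both report the
#' unweighted mean and the population SD (divide by n) of the finite T1
#' values; NaN pixels are excluded and counted. When the same pixel set is
#' produced by both routes the statistics are identical — the formal link
#' between the two measurement methods.
#'
#' @param map a [t1_map].
#' @param loi,roi geometry ([polyline_loi] / [polygon_roi]).
#' @param length_weighted if \code{TRUE}, `loi_stats()` weights each pixel
#'   by the chord length the polyline traverses inside it (sensitivity
#'   variant; the default replicates the plain pixels-crossed average).
#' @return object of class \code{sample_stats}: \code{pixel_set} (integer
#'   matrix, zero-based), \code{n}, \code{mean_t1}, \code{sd_t1},
#'   \code{n_nan_excluded}.
#' @export
loi_stats <- function(map, loi, length_weighted = FALSE) {
  stopifnot(inherits(map, "t1_map"))
  pix <- trace_loi_pixels(loi, dim(map$values))
  if (!length_weighted) return(.sample_stats(map, pix))
  w <- .chord_lengths(loi, pix)
  .sample_stats(map, pix, w)
}

#' @rdname loi_stats
#' @export
roi_stats <- function(map, roi) {
  stopifnot(inherits(map, "t1_map"))
  pix <- rasterize_polygon(roi, dim(map$values))
  .sample_stats(map, pix)
}

.sample_stats <- function(map, pix, w = NULL) {
  vals <- map$values[cbind(pix[, 1] + 1L, pix[, 2] + 1L)]
  ok <- is.finite(vals)
  if (!any(ok)) stop("all sampled pixels are NaN")
  v <- vals[ok]
  if (is.null(w)) {
    m <- mean(v)
    s <- sqrt(sum((v - m)^2) / length(v))      # population SD
  } else {
    w <- w[ok] / sum(w[ok])
    m <- sum(w * v)
    s <- sqrt(sum(w * (v - m)^2))
  }
  structure(list(pixel_set = pix, n = sum(ok), mean_t1 = m, sd_t1 = s,
                 n_nan_excluded = sum(!ok)),
            class = "sample_stats")
}

#' @export
print.sample_stats <- function(x, ...) {
  cat(sprintf("sample_stats: n = %d, mean T1 = %.1f ms, SD = %.1f ms (%d NaN excluded)\n",
              x$n, x$mean_t1, x$sd_t1, x$n_nan_excluded))
  invisible(x)
}

# chord length of the polyline inside each listed pixel, matched by (r, c)
.chord_lengths <- function(loi, pix) {
  key <- paste(pix[, 1], pix[, 2])
  acc <- stats::setNames(numeric(nrow(pix)), key)
  v <- loi$vertices
  for (i in seq_len(nrow(v) - 1L)) {
    p0 <- v[i, ]; p1 <- v[i + 1L, ]
    d <- p1 - p0
    ts <- c(0, 1)
    for (k in 1:2) {
      if (d[k] != 0) {
        lo <- min(p0[k], p1[k]); hi <- max(p0[k], p1[k])
        ln <- seq.int(ceiling(lo), floor(hi))
        ln <- ln[ln > lo & ln < hi]
        if (length(ln)) ts <- c(ts, (ln - p0[k]) / d[k])
      }
    }
    ts <- sort(unique(ts))
    seg_len <- sqrt(sum(d^2))
    mids <- (ts[-length(ts)] + ts[-1]) / 2
    pr <- p0[1] + mids * d[1]; pc <- p0[2] + mids * d[2]
    kk <- paste(floor(pr), floor(pc))
    len <- diff(ts) * seg_len
    hit <- kk %in% key & (pr != floor(pr)) & (pc != floor(pc))
    for (j in which(hit)) acc[[kk[j]]] <- acc[[kk[j]]] + len[j]
  }
  as.numeric(acc)
}

#' Maximum wall thickness over a region, in map pixels, with grade
#'
#' Thickness is measured on a supersampled binary myocardium mask as the
#' diameter of the largest inscribed disc: twice the maximum Euclidean
#' distance transform over the mask subpixels that fall inside the region
#' (the maximum of the EDT is attained on the mask skeleton, so no
#' explicit skeletonization is required). Because the EDT measures
#' center-to-center distance, thickness is \code{(2 * maxEDT - 1) /
#' supersample_factor}, with resolution one subpixel. Grades follow the
#' reading-protocol thresholds: grade 1 > 2 px, grade 2 = 1-2 px,
#' grade 3 < 1 px.
#'
#' @param myocardium_mask logical/0-1 matrix at \code{supersample_factor}
#'   times the map resolution.
#' @param region integer matrix of map-pixel indices (zero-based
#'   \code{row}, \code{col}) defining where to evaluate, e.g. an ROI's
#'   pixel set.
#' @param supersample_factor integer >= 1: mask subpixels per map pixel
#'   along each axis.
#' @return object of class \code{wall_thickness_grade}:
#'   \code{max_thickness_px}, \code{grade}.
#' @export
max_wall_thickness_px <- function(myocardium_mask, region, supersample_factor) {
  f <- as.integer(supersample_factor)
  stopifnot(f >= 1L, is.matrix(myocardium_mask), nrow(region) >= 1L)
  mask <- matrix(as.numeric(myocardium_mask != 0), nrow(myocardium_mask))
  # restrict to subpixels of the region's map pixels
  sel <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(region))) {
    rr <- region[i, 1] * f + seq_len(f)
    cc <- region[i, 2] * f + seq_len(f)
    sel[rr, cc] <- TRUE
  }
  if (!any(mask > 0 & sel))
    return(structure(list(max_thickness_px = 0, grade = 3L),
                     class = "wall_thickness_grade"))
  d <- EBImage::distmap(mask)
  maxd <- max(d[sel & mask > 0])
  thk <- max(0, (2 * maxd - 1)) / f
  structure(list(max_thickness_px = thk, grade = wall_grade(thk)),
            class = "wall_thickness_grade")
}

#' Wall-thickness grade from a thickness in pixels
#'
#' @param thickness_px maximum wall thickness in map pixels.
#' @return integer grade: 1 (> 2 px), 2 (1-2 px inclusive), 3 (< 1 px).
#' @export
wall_grade <- function(thickness_px) {
  stopifnot(is.finite(thickness_px), thickness_px >= 0)
  if (thickness_px > 2) 1L else if (thickness_px >= 1) 2L else 3L
}

#' @export
print.wall_thickness_grade <- function(x, ...) {
  cat(sprintf("max wall thickness %.2f px -> grade %d\n",
              x$max_thickness_px, x$grade))
  invisible(x)
}
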