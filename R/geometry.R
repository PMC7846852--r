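#' Operator geometry: polygon ROIs and polyline LOIs
#'
#' Geometry lives in continuous pixel coordinates \code{(row, col)}, origin
#' at the top-left corner of pixel \code{(0, 0)} (see [t1_map]). A
#' \code{polygon_roi} is an implicitly closed contour with at least three
#' vertices and positive area; a \code{polyline_loi} is an open curve with
#' at least two vertices, no two consecutive vertices identical, drawn by
#' the operator along the mid-wall of a thin structure.
#'
#' @param vertices two-column numeric matrix (row, col) of vertices.
#' @return \code{polygon_roi} / \code{polyline_loi} object.
#' @export
polygon_roi <- function(vertices) {
  vertices <- .as_vertex_matrix(vertices)
  if (nrow(vertices) < 3L) stop("a polygon ROI needs at least 3 vertices")
  if (abs(.polygon_area(vertices)) <= 0) stop("polygon ROI has zero area")
  if (.polygon_self_intersects(vertices))
    warning("polygon ROI is self-intersecting; even-odd rule applies")
  structure(list(vertices = vertices), class = "polygon_roi")
}

#' @rdname polygon_roi
#' @export
polyline_loi <- function(vertices) {
  vertices <- .as_vertex_matrix(vertices)
  if (nrow(vertices) < 2L) stop("a polyline LOI needs at least 2 vertices")
  d <- diff(vertices)
  if (any(rowSums(abs(d)) == 0))
    stop("polyline LOI has two identical consecutive vertices")
  structure(list(vertices = vertices), class = "polyline_loi")
}

.as_vertex_matrix <- function(v) {
  if (is.data.frame(v)) v <- as.matrix(v)
  if (is.list(v) && !is.matrix(v)) v <- do.call(rbind, v)
  v <- matrix(as.numeric(v), ncol = 2L,
              dimnames = list(NULL, c("row", "col")))
  if (any(!is.finite(v))) stop("geometry vertices must be finite")
  v
}

.polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(FALSE)
  seg <- cbind(v, v[c(2:n, 1L), ])
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next   # closing edge shares vertex 1
      if (.segments_cross(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(TRUE)
    }
  }
  FALSE
}

.segments_cross <- function(p1, p2, q1, q2) {
  o <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o(p1, p2, q1) * o(p1, p2, q2) < 0 && o(q1, q2, p1) * o(q1, q2, p2) < 0
}

#' Geometry set: named ROIs/LOIs with tissue tags
#'
#' @param rois named list of [polygon_roi].
#' @param lois named list of [polyline_loi].
#' @param tissue named character vector mapping every item name to one of
#'   \code{"RV_myocardium"}, \code{"LV_myocardium"}, \code{"blood_pool"}.
#' @return \code{geometry_set} object.
#' @export
geometry_set <- function(rois = list(), lois = list(), tissue = character()) {
  nm <- c(names(rois), names(lois))
  if (length(nm) != length(rois) + length(lois) || any(!nzchar(nm)))
    stop("all ROIs and LOIs must be named")
  if (anyDuplicated(nm)) stop("geometry names must be unique")
  tissues_ok <- c("RV_myocardium", "LV_myocardium", "blood_pool")
  if (!setequal(names(tissue), nm))
    stop("'tissue' must tag every geometry item exactly once")
  if (any(!tissue %in% tissues_ok))
    stop("tissue tags must be one of: ", paste(tissues_ok, collapse = ", "))
  for (r in rois) stopifnot(inherits(r, "polygon_roi"))
  for (l in lois) stopifnot(inherits(l, "polyline_loi"))
  structure(list(rois = rois, lois = lois, tissue = tissue[nm]),
            class = "geometry_set")
}

#' @export
print.geometry_set <- function(x, ...) {
  cat(sprintf("geometry set: %d ROI(s), %d LOI(s)\n",
              length(x$rois), length(x$lois)))
  for (nm in names(x$tissue))
    cat(sprintf("  %-16s %-14s %s\n", nm, x$tissue[[nm]],
                if (nm %in% names(x$rois)) "ROI" else "LOI"))
  invisible(x)
}

#' Read / write a geometry sidecar (JSON)
#'
#' Vertex lists are stored losslessly in continuous pixel coordinates.
#'
#' @param path JSON file.
#' @return [geometry_set] (reader) or \code{invisible(path)} (writer).
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  parse_item <- function(it, kind) {
    v <- do.call(rbind, lapply(it$vertices, function(p) as.numeric(unlist(p))))
    if (kind == "roi") polygon_roi(v) else polyline_loi(v)
  }
  rois <- lapply(j$rois, parse_item, kind = "roi")
  lois <- lapply(j$lois, parse_item, kind = "loi")
  tissue <- c(vapply(j$rois, function(it) it$tissue, ""),
              vapply(j$lois, function(it) it$tissue, ""))
  names(tissue) <- c(names(j$rois), names(j$lois))
  geometry_set(rois, lois, tissue)
}

#' @rdname read_geometry
#' @param set a [geometry_set].
#' @export
write_geometry <- function(set, path) {
  stopifnot(inherits(set, "geometry_set"))
  enc <- function(obj, nm) {
    list(tissue = set$tissue[[nm]],
         vertices = lapply(seq_len(nrow(obj$vertices)),
                           function(i) as.numeric(obj$vertices[i, ])))
  }
  out <- list(
    rois = mapply(enc, set$rois, names(set$rois), SIMPLIFY = FALSE),
    lois = mapply(enc, set$lois, names(set$lois), SIMPLIFY = FALSE)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Polyline length under anisotropic pixel spacing
#'
#' @param loi a [polyline_loi].
#' @param spacing (row_mm, col_mm) pixel spacing.
#' @return length in mm.
#' @export
polyline_length_mm <- function(loi, spacing) {
  stopifnot(inherits(loi, "polyline_loi"))
  d <- diff(loi$vertices)
  sum(sqrt((d[, 1] * spacing[1])^2 + (d[, 2] * spacing[2])^2))
}

#' Minimum-length rule for operator geometry
#'
#' The drawing protocol requires myocardial geometry at least 10 mm long.
#' An LOI is measured by its path length; an ROI by the longest chord
#' between any two of its vertices (the protocol states a "length", not an
#' area, for ROIs).
#'
#' @param geometry a [polyline_loi] or [polygon_roi].
#' @param spacing (row_mm, col_mm) pixel spacing.
#' @param min_mm minimum admissible length, default 10 mm.
#' @return list with \code{pass} and \code{length_mm}.
#' @export
validate_min_length <- function(geometry, spacing, min_mm = 10) {
  if (inherits(geometry, "polyline_loi")) {
    len <- polyline_length_mm(geometry, spacing)
  } else if (inherits(geometry, "polygon_roi")) {
    v <- geometry$vertices
    vs <- cbind(v[, 1] * spacing[1], v[, 2] * spacing[2])
    len <- max(dist(vs))
  } else stop("geometry must be a polyline_loi or polygon_roi")
  list(pass = len >= min_mm, length_mm = len)
}
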