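#' T1 parametric map
#'
#' Container for a single-slice T1 parametric map: a rectangular grid of
#' longitudinal relaxation times (ms) with pixel spacing metadata, an
#' acquisition phase (before or after contrast) and a slice orientation.
#'
#' Continuous coordinates are \code{(row, col)} with the origin at the
#' top-left corner of pixel \code{(0, 0)}; pixel \code{(r, c)} occupies the
#' half-open square \code{[r, r+1) x [c, c+1)} and its center is
#' \code{(r + 0.5, c + 0.5)}. Pixel indices are therefore zero-based
#' throughout the package; the underlying matrix is addressed as
#' \code{values[r + 1, c + 1]}.
#'
#' @param values numeric matrix of T1 values in ms; \code{NA}/\code{NaN}
#'   marks invalid pixels. Finite values must lie in \code{[0, 5000]} ms.
#' @param pixel_spacing numeric length-2, (row_mm, col_mm), both > 0.
#' @param phase \code{"native"} or \code{"post"}.
#' @param orientation slice orientation, \code{"SAX"} or \code{"TRANS"}.
#' @param subject_id subject identifier string.
#' @param acquisition_delay_min minutes between contrast bolus and
#'   acquisition (\code{NA} for native maps).
#' @return An object of class \code{t1_map}.
#' @export
t1_map <- function(values, pixel_spacing = c(1.9, 1.9),
                   phase = c("native", "post"),
                   orientation = c("SAX", "TRANS"),
                   subject_id = "", acquisition_delay_min = NA_real_) {
  phase <- match.arg(phase)
  orientation <- match.arg(orientation)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) < 8L || ncol(values) < 8L)
    stop("T1 map grid must be at least 8x8")
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) != 2L || any(!is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0))
    stop("'pixel_spacing' must be two strictly positive numbers (mm)")
  fin <- values[is.finite(values)]
  if (length(fin) && (min(fin) < 0 || max(fin) > 5000))
    stop("finite T1 values must lie within the plausibility bound [0, 5000] ms")
  structure(list(values = values,
                 pixel_spacing = pixel_spacing,
                 phase = phase, orientation = orientation,
                 subject_id = as.character(subject_id),
                 acquisition_delay_min = as.numeric(acquisition_delay_min)),
            class = "t1_map")
}

#' @export
print.t1_map <- function(x, ...) {
  d <- dim(x$values)
  fin <- x$values[is.finite(x$values)]
  cat(sprintf("T1 map [%s, %s]%s: %d x %d px @ %.3g x %.3g mm\n",
              x$phase, x$orientation,
              if (nzchar(x$subject_id)) paste0(" subject ", x$subject_id) else "",
              d[1], d[2], x$pixel_spacing[1], x$pixel_spacing[2]))
  cat(sprintf("  T1 range %.1f-%.1f ms, %d invalid pixel(s)\n",
              if (length(fin)) min(fin) else NA, if (length(fin)) max(fin) else NA,
              sum(!is.finite(x$values))))
  invisible(x)
}

#' @export
dim.t1_map <- function(x) dim(x$values)

#' Read a T1 map from disk
#'
#' Supports two dialects: single-frame DICOM (\code{PixelSpacing} required;
#' values stored as unsigned 16-bit with RescaleSlope/Intercept) and a
#' plain-text matrix whose first line is
#' \code{"rows cols spacing_r spacing_c phase orientation"} followed by the
#' whitespace-separated values, \code{nan} marking invalid pixels.
#'
#' Pixels outside the plausibility bound (negative or above 5000 ms) are
#' replaced by \code{NaN} and counted in the load report attached as
#' \code{attr(map, "load_report")}.
#'
#' @param path file to read.
#' @param dialect \code{"text_matrix"} or \code{"dicom"}; default guesses
#'   from the file content.
#' @return a [t1_map] with a \code{load_report} attribute
#'   (\code{n_implausible}: pixels forced to NaN on load).
#' @export
read_t1map <- function(path, dialect = c("auto", "text_matrix", "dicom")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    magic <- readBin(path, "raw", n = 132L)
    dialect <- if (length(magic) >= 132L &&
                   rawToChar(magic[129:132]) == "DICM") "dicom" else "text_matrix"
  }
  raw <- switch(dialect,
                text_matrix = .read_t1map_text(path),
                dicom = .read_t1map_dicom(path))
  v <- raw$values
  bad <- is.finite(v) & (v < 0 | v > 5000)
  v[bad] <- NaN
  map <- t1_map(v, pixel_spacing = raw$pixel_spacing, phase = raw$phase,
                orientation = raw$orientation, subject_id = raw$subject_id,
                acquisition_delay_min = raw$acquisition_delay_min)
  attr(map, "load_report") <- list(n_implausible = sum(bad))
  map
}

#' Write a T1 map to disk
#'
#' Inverse of [read_t1map]: the text dialect stores full precision, the
#' DICOM dialect quantizes to unsigned 16-bit via \code{RescaleSlope}
#' (default 0.1 ms, so the maximum round-trip error is slope/2) and stores
#' \code{NaN} as the sentinel word 0xFFFF.
#'
#' @param map a [t1_map].
#' @param path destination file.
#' @param dialect \code{"text_matrix"} or \code{"dicom"}.
#' @param slope DICOM RescaleSlope in ms per stored unit.
#' @return \code{invisible(path)}.
#' @export
write_t1map <- function(map, path, dialect = c("text_matrix", "dicom"),
                        slope = 0.1) {
  stopifnot(inherits(map, "t1_map"))
  dialect <- match.arg(dialect)
  switch(dialect,
         text_matrix = .write_t1map_text(map, path),
         dicom = .write_t1map_dicom(map, path, slope = slope))
  invisible(path)
}

.read_t1map_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty text matrix file")
  hdr <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  if (length(hdr) != 6L)
    stop("text dialect header must be 'rows cols spacing_r spacing_c phase orientation'")
  nr <- as.integer(hdr[1]); nc <- as.integer(hdr[2])
  sp <- as.numeric(hdr[3:4])
  toks <- unlist(strsplit(trimws(lines[-1]), "[[:space:]]+"), use.names = FALSE)
  per_row <- vapply(strsplit(trimws(lines[-1]), "[[:space:]]+"), length, 1L)
  if (length(unique(per_row)) > 1L || length(toks) != nr * nc)
    stop("non-rectangular text matrix: expected ", nr, "x", nc, " values")
  vals <- suppressWarnings(as.numeric(tolower(toks)))
  vals[tolower(toks) %in% c("nan", "na")] <- NaN
  if (anyNA(vals) && any(is.na(vals) & !tolower(toks) %in% c("nan", "na")))
    stop("unparseable value in text matrix")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  list(values = m, pixel_spacing = sp, phase = hdr[5], orientation = hdr[6],
       subject_id = "", acquisition_delay_min = NA_real_)
}

.write_t1map_text <- function(map, path) {
  d <- dim(map$values)
  hdr <- paste(d[1], d[2],
               format(map$pixel_spacing[1], digits = 17),
               format(map$pixel_spacing[2], digits = 17),
               map$phase, map$orientation)
  body <- apply(map$values, 1L, function(r) {
    r <- format(r, digits = 17, trim = TRUE, scientific = FALSE)
    r[r %in% c("NA", "NaN")] <- "nan"
    paste(r, collapse = " ")
  })
  writeLines(c(hdr, body), path)
}
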