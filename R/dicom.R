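# Minimal single-frame DICOM (Explicit VR Little Endian) reader/writer for
# T1 parametric maps. Only the tags the package needs are emitted; the
# reader is a generic explicit-VR walker, so files written by mainstream
# tools parse as long as they use the 1.2.840.10008.1.2.1 transfer syntax.

.dicom_uid_root <- "1.2.826.0.1.3680043.10.1217"

.dicom_new_uid <- function() {
  paste0(.dicom_uid_root, ".",
         format(as.integer(Sys.time())), ".",
         sample.int(.Machine$integer.max, 1L))
}

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) {
  # unsigned 32-bit little-endian without overflowing R's signed int
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

.dicom_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L)
    value_raw <- c(value_raw, as.raw(if (vr %in% c("UI")) 0L else 32L))
  head <- c(.u16(group), .u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), .u32(length(value_raw)), value_raw)
  } else {
    c(head, .u16(length(value_raw)), value_raw)
  }
}

.dicom_str <- function(group, elem, vr, s) .dicom_element(group, elem, vr, charToRaw(s))
.dicom_us  <- function(group, elem, x) .dicom_element(group, elem, "US", .u16(x))

.write_t1map_dicom <- function(map, path, slope = 0.1) {
  if (slope <= 0) stop("RescaleSlope must be positive")
  v <- map$values
  stored <- round(v / slope)
  stored[!is.finite(v)] <- 65535           # NaN sentinel
  if (any(stored[is.finite(v)] > 65534))
    stop("values exceed the 16-bit range at this RescaleSlope")
  # DICOM PixelData is row-major (top-left, across columns first)
  px <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")

  sop_uid <- .dicom_new_uid()
  desc <- sprintf("T1MAP;phase=%s;orient=%s;delay=%s", map$phase,
                  map$orientation,
                  if (is.na(map$acquisition_delay_min)) "NA"
                  else format(map$acquisition_delay_min))
  ds <- c(
    .dicom_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.7"),
    .dicom_str(0x0008, 0x0018, "UI", sop_uid),
    .dicom_str(0x0008, 0x0060, "CS", "MR"),
    .dicom_str(0x0008, 0x103E, "LO", desc),
    .dicom_str(0x0010, 0x0020, "LO", map$subject_id),
    .dicom_us (0x0028, 0x0002, 1L),
    .dicom_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dicom_us (0x0028, 0x0010, nrow(v)),
    .dicom_us (0x0028, 0x0011, ncol(v)),
    .dicom_str(0x0028, 0x0030, "DS",
               paste(format(map$pixel_spacing[1], digits = 10),
                     format(map$pixel_spacing[2], digits = 10), sep = "\\")),
    .dicom_us (0x0028, 0x0100, 16L),
    .dicom_us (0x0028, 0x0101, 16L),
    .dicom_us (0x0028, 0x0102, 15L),
    .dicom_us (0x0028, 0x0103, 0L),
    .dicom_str(0x0028, 0x1052, "DS", "0"),
    .dicom_str(0x0028, 0x1053, "DS", format(slope, digits = 10)),
    .dicom_element(0x7FE0, 0x0010, "OW", px)
  )
  meta <- c(
    .dicom_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .dicom_str(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.7"),
    .dicom_str(0x0002, 0x0003, "UI", sop_uid),
    .dicom_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    .dicom_str(0x0002, 0x0012, "UI", .dicom_uid_root)
  )
  meta <- c(.dicom_element(0x0002, 0x0000, "UL", .u32(length(meta))), meta)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

# walk an explicit-VR-little-endian byte stream, returning a named list of
# raw values keyed "gggg,eeee"
.dicom_parse <- function(bytes) {
  n <- length(bytes)
  pos <- 1L
  rd_u16 <- function(at) readBin(bytes[at:(at + 1L)], "integer", size = 2,
                                 endian = "little", signed = FALSE)
  rd_u32 <- function(at) sum(as.numeric(bytes[at:(at + 3L)]) * 256^(0:3))
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= n) {
    group <- rd_u16(pos); elem <- rd_u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- rd_u32(pos + 8L); val_at <- pos + 12L
    } else {
      len <- rd_u16(pos + 6L); val_at <- pos + 8L
    }
    if (len > n - val_at + 1L) stop("truncated DICOM element")
    key <- sprintf("%04x,%04x", group, elem)
    out[[key]] <- if (len > 0) bytes[val_at:(val_at + len - 1L)] else raw(0)
    pos <- val_at + len
  }
  out
}

.dicom_elem_str <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el))
}

.read_t1map_dicom <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  el <- .dicom_parse(bytes[-(1:132)])
  ts <- .dicom_elem_str(el[["0002,0010"]])
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1")
    stop("unsupported DICOM transfer syntax: ", ts)
  sp_raw <- el[["0028,0030"]]
  if (is.null(sp_raw)) stop("DICOM file lacks PixelSpacing (0028,0030)")
  sp <- as.numeric(strsplit(.dicom_elem_str(sp_raw), "\\\\")[[1]])
  rows <- readBin(el[["0028,0010"]], "integer", size = 2, endian = "little",
                  signed = FALSE)
  cols <- readBin(el[["0028,0011"]], "integer", size = 2, endian = "little",
                  signed = FALSE)
  slope <- .dicom_elem_str(el[["0028,1053"]])
  slope <- if (is.null(slope)) 1 else as.numeric(slope)
  icpt <- .dicom_elem_str(el[["0028,1052"]])
  icpt <- if (is.null(icpt)) 0 else as.numeric(icpt)
  px_raw <- el[["7fe0,0010"]]
  if (is.null(px_raw)) stop("DICOM file lacks PixelData")
  stored <- readBin(px_raw, "integer", n = rows * cols, size = 2,
                    endian = "little", signed = FALSE)
  v <- stored * slope + icpt
  v[stored == 65535L] <- NaN
  m <- t(matrix(v, nrow = cols, ncol = rows))   # stream is row-major
  phase <- "native"; orient <- "SAX"; delay <- NA_real_
  desc <- .dicom_elem_str(el[["0008,103e"]])
  if (!is.null(desc)) {
    f <- regmatches(desc, regexec("phase=([a-z]+);orient=([A-Z]+);delay=([^;]+)", desc))[[1]]
    if (length(f) == 4L) {
      phase <- f[2]; orient <- f[3]
      delay <- suppressWarnings(as.numeric(f[4]))
    }
  }
  subj <- .dicom_elem_str(el[["0010,0020"]])
  list(values = m, pixel_spacing = sp, phase = phase, orientation = orient,
       subject_id = if (is.null(subj)) "" else subj,
       acquisition_delay_min = delay)
}
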