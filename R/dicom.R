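# Minimal DICOM RT Dose reader.
#
# Parses little-endian DICOM files (explicit or implicit VR) far enough to
# recover a planar dose grid: Rows, Columns, PixelSpacing, BitsAllocated,
# PixelRepresentation, NumberOfFrames, GridFrameOffsetVector,
# ImagePositionPatient, DoseGridScaling and PixelData. Sequences with
# defined or undefined length are skipped. This is deliberately not a
# general DICOM implementation; it covers the RT Dose planar export this
# pipeline consumes.

is_dicom <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 132)
  length(hdr) == 132 && rawToChar(hdr[129:132]) == "DICM"
}

# VRs whose explicit encoding uses a 2-byte reserved field + 4-byte length
long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

dicom_elements <- function(raw) {
  pos <- 1L
  n <- length(raw)
  u16 <- function(p) as.integer(raw[p]) + 256L * as.integer(raw[p + 1L])
  u32 <- function(p) as.integer(raw[p]) + 256 * as.integer(raw[p + 1L]) +
    65536 * as.integer(raw[p + 2L]) + 16777216 * as.integer(raw[p + 3L])
  out <- list()
  explicit <- NA   # decided at the first post-meta element
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    tag <- sprintf("%04X,%04X", group, elem)
    if (group == 0xFFFE) {               # item / delimiter
      pos <- pos + 8L
      next
    }
    meta <- group == 0x0002              # file meta group is always explicit
    vr_bytes <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    this_explicit <- if (meta) TRUE else {
      if (is.na(explicit)) explicit <- grepl("^[A-Z]{2}$", vr_bytes)
      explicit
    }
    if (this_explicit) {
      vr <- vr_bytes
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- ""
      len <- u32(pos + 4L); hdr <- 8L
    }
    if (len == 4294967295 || (identical(vr, "SQ"))) {   # undefined length / SQ
      # scan forward for the matching sequence delimitation item
      if (len == 4294967295) {
        p <- pos + hdr
        depth <- 1L
        while (p + 7L <= n && depth > 0L) {
          g <- u16(p); e <- u16(p + 2L)
          if (g == 0xFFFE && e == 0xE0DD) depth <- depth - 1L
          p <- p + 8L
        }
        pos <- p
      } else {
        pos <- pos + hdr + len
      }
      next
    }
    value <- raw[(pos + hdr):(pos + hdr + len - 1L)]
    out[[tag]] <- list(vr = vr, value = value)
    pos <- pos + hdr + len
  }
  out
}

dicom_string <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$value))
}

dicom_numeric <- function(el) {
  s <- dicom_string(el)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dicom_uint16le <- function(el) {
  v <- el$value
  readBin(v, "integer", n = length(v) / 2, size = 2, signed = FALSE,
          endian = "little")
}

dicom_uint32le <- function(el) {
  v <- el$value
  x <- readBin(v, "integer", n = length(v) / 4, size = 4, endian = "little")
  x[x < 0] <- x[x < 0] + 4294967296
  x
}

#' Read a planar dose grid from a DICOM RT Dose file
#'
#' Little-endian (explicit or implicit VR) RT Dose files are parsed with a
#' purpose-built minimal reader; stored pixel values are multiplied by
#' `DoseGridScaling` to give Gy. For multi-frame dose grids a single frame
#' must be selected with `frame`. The in-plane geometry uses `PixelSpacing`
#' (row spacing, column spacing); patient-coordinate placement is outside
#' the scope of planar QA, so unless `origin_mm` is given the plane is
#' centered on the isocenter.
#'
#' @param path RT Dose file path
#' @param frame frame to extract (1-based); `NULL` accepts single-frame
#'   files only
#' @param origin_mm optional `c(x, y)` origin override in mm
#' @return a [dose_plane()] with `provenance = "plan"`
#' @export
read_dicom_rtdose <- function(path, frame = NULL, origin_mm = NULL) {
  if (!is_dicom(path)) stop("read_dicom_rtdose: not a DICOM file: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  els <- dicom_elements(raw[-(1:132)])
  rows <- dicom_uint16le(els[["0028,0010"]])
  cols <- dicom_uint16le(els[["0028,0011"]])
  if (!length(rows) || !length(cols))
    stop("read_dicom_rtdose: missing Rows/Columns")
  spacing <- dicom_numeric(els[["0028,0030"]])   # row spacing, col spacing
  if (is.null(spacing)) stop("read_dicom_rtdose: missing PixelSpacing")
  scaling <- dicom_numeric(els[["3004,000E"]])
  if (is.null(scaling))
    stop("read_dicom_rtdose: missing DoseGridScaling tag")
  bits <- dicom_uint16le(els[["0028,0100"]])
  if (!length(bits)) bits <- 16L
  nframes <- dicom_numeric(els[["0028,0008"]]) %||% 1
  pix <- els[["7FE0,0010"]]
  if (is.null(pix)) stop("read_dicom_rtdose: missing PixelData")
  stored <- if (bits == 32) dicom_uint32le(pix) else dicom_uint16le(pix)
  if (nframes > 1) {
    if (is.null(frame))
      stop("read_dicom_rtdose: multi-frame dose grid; select a frame")
    if (frame < 1 || frame > nframes)
      stop("read_dicom_rtdose: frame out of range 1..", nframes)
    per <- rows * cols
    stored <- stored[((frame - 1) * per + 1):(frame * per)]
  }
  dose <- matrix(stored * scaling, nrow = rows, ncol = cols, byrow = TRUE)
  dose_plane(dose, spacing_mm = c(spacing[2], spacing[1]),
             origin_mm = origin_mm, provenance = "plan",
             label = basename(path))
}
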