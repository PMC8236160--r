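# Minimal explicit-VR little-endian DICOM RT Dose writer, used only to build
# test fixtures in code (independent of the package's reader).

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1) value_raw <- c(value_raw, as.raw(0))
  hdr <- c(dcm_u16(group), dcm_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "UN", "UT", "SQ")) {
    c(hdr, as.raw(c(0, 0)), dcm_u32(length(value_raw)), value_raw)
  } else {
    c(hdr, dcm_u16(length(value_raw)), value_raw)
  }
}

dcm_str <- function(group, elem, vr, s) dcm_element(group, elem, vr, charToRaw(s))

write_test_rtdose <- function(path, stored, scaling, spacing = c(1, 1)) {
  if (!is.list(stored)) stored <- list(stored)
  n_frames <- length(stored)
  rows <- nrow(stored[[1]]); cols <- ncol(stored[[1]])
  pix <- do.call(c, lapply(stored, function(m)
    writeBin(as.integer(t(m)), raw(), size = 2, endian = "little")))
  meta <- c(
    dcm_element(0x0002, 0x0010, "UI",
                charToRaw("1.2.840.10008.1.2.1"))   # explicit VR LE
  )
  body <- c(
    dcm_str(0x0008, 0x0060, "CS", "RTDOSE"),
    if (n_frames > 1) dcm_str(0x0028, 0x0008, "IS", as.character(n_frames)),
    dcm_element(0x0028, 0x0010, "US", dcm_u16(rows)),
    dcm_element(0x0028, 0x0011, "US", dcm_u16(cols)),
    dcm_str(0x0028, 0x0030, "DS",
            sprintf("%g\\%g", spacing[1], spacing[2])),
    dcm_element(0x0028, 0x0100, "US", dcm_u16(16)),
    dcm_element(0x0028, 0x0103, "US", dcm_u16(0)),
    dcm_str(0x3004, 0x000E, "DS", sprintf("%.10g", scaling)),
    dcm_element(0x7FE0, 0x0010, "OW", pix)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}
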