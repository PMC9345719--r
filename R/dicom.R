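# Minimal single-frame DICOM reader.
#
# Supports the two uncompressed little-endian transfer syntaxes
# (implicit VR 1.2.840.10008.1.2 and explicit VR 1.2.840.10008.1.2.1),
# monochrome photometric interpretations, 8- or 16-bit pixels, signed or
# unsigned. Compressed syntaxes, big-endian files and multi-frame objects
# are rejected. This is deliberately a small parser for CT slice input, not
# a general DICOM toolkit.

UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

# VRs whose explicit encoding uses a 2-byte reserved field + 4-byte length.
LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

dcm_uint16 <- function(raw2) {
  as.integer(raw2[1]) + 256L * as.integer(raw2[2])
}
dcm_uint32 <- function(raw4) {
  as.numeric(raw4[1]) + 256 * as.numeric(raw4[2]) +
    65536 * as.numeric(raw4[3]) + 16777216 * as.numeric(raw4[4])
}

# Parse a dataset region, returning a list keyed by "gggg,eeee" with raw
# value fields. Stops after PixelData.
dcm_parse_elements <- function(bytes, pos, end, explicit) {
  out <- list()
  while (pos + 7 <= end) {
    group <- dcm_uint16(bytes[pos:(pos + 1)])
    elem <- dcm_uint16(bytes[(pos + 2):(pos + 3)])
    pos <- pos + 4
    vr <- NULL
    if (explicit) {
      vr <- rawToChar(bytes[pos:(pos + 1)])
      if (vr %in% LONG_VRS) {
        len <- dcm_uint32(bytes[(pos + 4):(pos + 7)])
        pos <- pos + 8
      } else {
        len <- dcm_uint16(bytes[(pos + 2):(pos + 3)])
        pos <- pos + 4
      }
    } else {
      len <- dcm_uint32(bytes[pos:(pos + 3)])
      pos <- pos + 4
    }
    if (len == 4294967295) {  # undefined length (sequences / encapsulation)
      stop_io("unsupported DICOM element with undefined length (%04x,%04x)",
              group, elem)
    }
    key <- sprintf("%04x,%04x", group, elem)
    value <- if (len > 0) bytes[pos:(pos + len - 1)] else raw(0)
    out[[key]] <- list(vr = vr, value = value)
    pos <- pos + len
    if (key == "7fe0,0010") break
  }
  list(elements = out, pos = pos)
}

dcm_string <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$value))
}
dcm_number <- function(el) {
  s <- dcm_string(el)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]][1])
}
dcm_us <- function(el) {
  if (is.null(el)) return(NULL)
  dcm_uint16(el$value[1:2])
}

read_dicom_image <- function(path, windowing = NULL) {
  n <- file.size(path)
  bytes <- readBin(path, "raw", n = n)
  if (n < 132 || !identical(rawToChar(bytes[129:132]), "DICM")) {
    stop_io("not a DICOM file (missing DICM preamble): %s", path)
  }
  # File meta information (group 0002) is always explicit VR little endian.
  meta <- dcm_parse_elements_group2(bytes, 133L)
  ts <- dcm_string(meta$elements[["0002,0010"]]) %||% UID_EXPLICIT_LE
  if (!ts %in% c(UID_IMPLICIT_LE, UID_EXPLICIT_LE)) {
    stop_io("unsupported DICOM transfer syntax %s (compressed or big endian)", ts)
  }
  ds <- dcm_parse_elements(bytes, meta$pos, n, explicit = ts == UID_EXPLICIT_LE)
  el <- ds$elements

  frames <- dcm_number(el[["0028,0008"]])
  if (!is.null(frames) && frames > 1) {
    stop_io("multi-frame DICOM is not supported (%d frames): %s", frames, path)
  }
  rows <- dcm_us(el[["0028,0010"]])
  cols <- dcm_us(el[["0028,0011"]])
  bits <- dcm_us(el[["0028,0100"]]) %||% 16L
  signed <- identical(dcm_us(el[["0028,0103"]]), 1L)
  if (is.null(rows) || is.null(cols)) {
    stop_io("DICOM file lacks Rows/Columns: %s", path)
  }
  px <- el[["7fe0,0010"]]
  if (is.null(px)) stop_io("DICOM file has no PixelData: %s", path)
  npix <- rows * cols
  if (bits == 8L) {
    v <- readBin(px$value, "integer", n = npix, size = 1L, signed = signed)
  } else if (bits == 16L) {
    v <- readBin(px$value, "integer", n = npix, size = 2L, signed = signed,
                 endian = "little")
    if (!signed) v <- ifelse(v < 0, v + 65536L, v)  # readBin size-2 unsigned fix
  } else {
    stop_io("unsupported BitsAllocated = %d: %s", bits, path)
  }
  if (length(v) < npix) stop_io("truncated DICOM PixelData: %s", path)
  slope <- dcm_number(el[["0028,1053"]]) %||% 1
  intercept <- dcm_number(el[["0028,1052"]]) %||% 0
  hu <- matrix(v * slope + intercept, nrow = rows, ncol = cols, byrow = TRUE)

  if (is.null(windowing)) {
    wc <- dcm_number(el[["0028,1050"]])
    ww <- dcm_number(el[["0028,1051"]])
    windowing <- if (!is.null(wc) && !is.null(ww) && ww > 0) {
      windowing_spec(wc, ww)
    } else {
      windowing_spec()  # abdominal soft-tissue preset
    }
  }
  apply_windowing(hu, windowing)
}

# Group-0002 parser: explicit VR, stops when the group changes.
dcm_parse_elements_group2 <- function(bytes, pos) {
  out <- list()
  n <- length(bytes)
  while (pos + 7 <= n) {
    group <- dcm_uint16(bytes[pos:(pos + 1)])
    if (group != 2L) break
    elem <- dcm_uint16(bytes[(pos + 2):(pos + 3)])
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (vr %in% LONG_VRS) {
      len <- dcm_uint32(bytes[(pos + 10):(pos + 13)])
      pos <- pos + 14
    } else {
      len <- dcm_uint16(bytes[(pos + 6):(pos + 7)])
      pos <- pos + 8
    }
    key <- sprintf("%04x,%04x", group, elem)
    out[[key]] <- list(vr = vr,
                       value = if (len > 0) bytes[pos:(pos + len - 1)] else raw(0))
    pos <- pos + len
  }
  list(elements = out, pos = pos)
}
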