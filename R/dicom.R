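# Minimal single-frame grayscale DICOM codec (Explicit/Implicit VR Little
# Endian, MONOCHROME1/2, 8- or 16-bit). Covers the uncompressed files
# digital mammography systems export; compressed transfer syntaxes are
# rejected with an explicit error.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_SC_STORAGE <- "1.2.840.10008.5.1.4.1.1.7"  # secondary capture

u16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
u32 <- function(raw4) sum(as.numeric(raw4) * 256^(0:3))

# string values are NUL- (UI) or space-padded
raw_string <- function(v) trimws(rawToChar(v[v != as.raw(0L)]))

long_vrs <- c("OB", "OW", "OF", "OL", "SQ", "UT", "UN", "UC", "UR")

#' Read a DICOM file
#'
#' Supports uncompressed Explicit and Implicit VR Little Endian transfer
#' syntaxes with single-frame MONOCHROME1/MONOCHROME2 pixel data at 8 or 16
#' bits. MONOCHROME1 intensities are inverted so brighter always means
#' higher. Other transfer syntaxes (in particular compressed ones) raise a
#' format error.
#'
#' @param path file path.
#' @return list with \code{pixels} (numeric matrix, rows = image rows),
#'   \code{rows}, \code{cols}, \code{bitsAllocated},
#'   \code{photometric}.
#' @export
readDicom <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM part-10 file (missing DICM magic): ", path)
  pos <- 133L
  explicit <- TRUE      # file meta group is always explicit VR
  ts <- NULL
  tags <- list()
  while (pos + 8L <= length(bytes) + 1L) {
    group <- u16(bytes[pos:(pos + 1L)])
    elem <- u16(bytes[(pos + 2L):(pos + 3L)])
    pos <- pos + 4L
    if (group != 0x0002L && !is.null(ts) && ts == UID_IMPLICIT_LE)
      explicit <- FALSE
    if (explicit) {
      vr <- rawToChar(bytes[pos:(pos + 1L)])
      if (vr %in% long_vrs) {
        len <- u32(bytes[(pos + 4L):(pos + 7L)])
        pos <- pos + 8L
      } else {
        len <- u16(bytes[(pos + 2L):(pos + 3L)])
        pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- u32(bytes[pos:(pos + 3L)])
      pos <- pos + 4L
    }
    if (len > length(bytes) - pos + 1L)
      stop("truncated DICOM element (", sprintf("%04x,%04x", group, elem),
           ") in ", path)
    val <- bytes[seq.int(pos, length.out = len)]
    pos <- pos + len
    key <- sprintf("%04x,%04x", group, elem)
    tags[[key]] <- val
    if (key == "0002,0010") {
      ts <- raw_string(val)
      if (!ts %in% c(UID_EXPLICIT_LE, UID_IMPLICIT_LE))
        stop("unsupported DICOM transfer syntax ", ts,
             " (only uncompressed little endian is handled): ", path)
    }
    if (key == "7fe0,0010") break
  }
  need16 <- function(key, default = NULL) {
    v <- tags[[key]]
    if (is.null(v)) {
      if (is.null(default)) stop("DICOM tag (", key, ") missing in ", path)
      return(default)
    }
    u16(v[1:2])
  }
  rows <- need16("0028,0010"); cols <- need16("0028,0011")
  bits <- need16("0028,0100")
  pixrep <- need16("0028,0103", 0L)
  photo <- if (!is.null(tags[["0028,0004"]]))
    raw_string(tags[["0028,0004"]]) else "MONOCHROME2"
  pd <- tags[["7fe0,0010"]]
  if (is.null(pd)) stop("no pixel data in ", path)
  n <- rows * cols
  v <- if (bits == 8L) {
    as.numeric(as.integer(pd[seq_len(n)]))
  } else if (bits == 16L) {
    readBin(pd, "integer", n = n, size = 2L, signed = pixrep == 1L,
            endian = "little")
  } else stop("unsupported BitsAllocated ", bits, " in ", path)
  if (bits == 16L && pixrep == 0L) v[v < 0] <- v[v < 0] + 65536
  m <- matrix(as.numeric(v), rows, cols, byrow = TRUE)
  if (photo == "MONOCHROME1") m <- max(m) - m
  list(pixels = m, rows = rows, cols = cols, bitsAllocated = bits,
       photometric = photo)
}

# -- writer ------------------------------------------------------------------

raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                endian = "little")
raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                endian = "little")

dcm_element <- function(group, elem, vr, value) {
  if (vr %in% c("UI", "CS", "SH", "LO")) {
    padByte <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    value <- charToRaw(value)
    if (length(value) %% 2L) value <- c(value, padByte)
  } else if (vr == "US") {
    value <- raw_u16(value)
  }
  head <- c(raw_u16(group), raw_u16(elem), charToRaw(vr))
  if (vr %in% long_vrs)
    c(head, as.raw(c(0L, 0L)), raw_u32(length(value)), value)
  else
    c(head, raw_u16(length(value)), value)
}

#' Write a minimal grayscale DICOM file
#'
#' Emits an Explicit VR Little Endian secondary-capture file with a single
#' MONOCHROME1 or MONOCHROME2 frame at 8 or 16 bits -- enough structure for
#' any standards-conforming reader. Intended for fixtures and for exporting
#' phantoms in the clinical input format.
#'
#' @param pixels integer matrix (rows = image rows) of nonnegative values
#'   within the chosen bit depth.
#' @param path output file.
#' @param bits 8 or 16.
#' @param photometric "MONOCHROME2" (default; higher = brighter) or
#'   "MONOCHROME1".
#' @return the path, invisibly.
#' @export
writeDicom <- function(pixels, path, bits = 16L,
                       photometric = c("MONOCHROME2", "MONOCHROME1")) {
  photometric <- match.arg(photometric)
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16")
  if (any(pixels < 0) || any(pixels >= 2^bits))
    stop("pixel values must lie in [0, 2^bits)")
  v <- as.integer(t(pixels))            # row-major order
  pd <- if (bits == 8L) as.raw(v)
        else writeBin(ifelse(v > 32767L, v - 65536L, v), raw(), size = 2L,
                      endian = "little")
  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_element(0x0002, 0x0002, "UI", UID_SC_STORAGE),
    dcm_element(0x0002, 0x0003, "UI", "1.2.826.0.1.3680043.8.498.1"),
    dcm_element(0x0002, 0x0010, "UI", UID_EXPLICIT_LE))
  dataset <- c(
    dcm_element(0x0008, 0x0016, "UI", UID_SC_STORAGE),
    dcm_element(0x0008, 0x0018, "UI", "1.2.826.0.1.3680043.8.498.1"),
    dcm_element(0x0028, 0x0002, "US", 1L),
    dcm_element(0x0028, 0x0004, "CS", photometric),
    dcm_element(0x0028, 0x0010, "US", nrow(pixels)),
    dcm_element(0x0028, 0x0011, "US", ncol(pixels)),
    dcm_element(0x0028, 0x0100, "US", bits),
    dcm_element(0x0028, 0x0101, "US", bits),
    dcm_element(0x0028, 0x0102, "US", bits - 1L),
    dcm_element(0x0028, 0x0103, "US", 0L),
    dcm_element(0x7fe0, 0x0010, "OW", pd))
  out <- c(raw(128L), charToRaw("DICM"),
           dcm_element(0x0002, 0x0000, "UL", raw_u32(length(meta))),
           meta, dataset)
  writeBin(out, path)
  invisible(path)
}
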