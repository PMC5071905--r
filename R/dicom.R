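# Minimal DICOM support for the images this package consumes: uncompressed
# single-frame 8-bit grayscale, explicit or implicit VR little endian.
# Scanner exports beyond that (compressed transfer syntaxes, multi-frame
# cine loops, >8-bit data) are rejected rather than guessed at.

DICOM_TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
DICOM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

is_dicom_file <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 132L)
  length(hdr) == 132L && rawToChar(hdr[129:132]) == "DICM"
}

u16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
u32 <- function(raw4) sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))

#' Read a single-frame 8-bit grayscale DICOM file
#'
#' Supports explicit and implicit VR little endian transfer syntaxes.
#' `MONOCHROME1` pixel data (larger value = darker) is inverted to the
#' `MONOCHROME2` convention on load so that gray values are always
#' brightness. Multi-frame files and bit depths other than 8 raise an
#' `echoquant_unsupported` error.
#'
#' @param path path to the DICOM file.
#' @return A [gray_image].
#' @export
read_dicom_gray <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM")
    eq_error("echoquant_format", "not a DICOM part-10 file (missing DICM magic)")
  pos <- 133L
  explicit <- TRUE        # file meta group is always explicit VR LE
  ts <- DICOM_TS_EXPLICIT_LE
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(bytes)) {
    group <- u16(bytes[pos:(pos + 1L)]); elem <- u16(bytes[(pos + 2L):(pos + 3L)])
    pos <- pos + 4L
    if (group != 0x0002 && !identical(ts, "locked")) {
      # leaving the file meta: switch to the dataset's transfer syntax
      if (!(ts %in% c(DICOM_TS_EXPLICIT_LE, DICOM_TS_IMPLICIT_LE)))
        eq_error("echoquant_unsupported", paste("unsupported transfer syntax:", ts))
      explicit <- identical(ts, DICOM_TS_EXPLICIT_LE)
      ts <- "locked"
    }
    if (explicit || group == 0x0002) {
      vr <- rawToChar(bytes[pos:(pos + 1L)]); pos <- pos + 2L
      if (vr %in% long_vrs) {
        pos <- pos + 2L  # reserved
        len <- u32(bytes[pos:(pos + 3L)]); pos <- pos + 4L
      } else {
        len <- u16(bytes[pos:(pos + 1L)]); pos <- pos + 2L
      }
    } else {
      vr <- NA_character_
      len <- u32(bytes[pos:(pos + 3L)]); pos <- pos + 4L
    }
    if (len == 4294967295) # undefined length (sequences / encapsulated data)
      eq_error("echoquant_unsupported", "undefined-length DICOM elements are not supported")
    val <- if (len > 0L) bytes[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    key <- sprintf("%04X,%04X", group, elem)
    tags[[key]] <- list(vr = vr, bytes = val)
    if (group == 0x0002 && elem == 0x0010)
      ts <- trimws(rawToChar(val[val != as.raw(0)]))
    if (group == 0x7FE0 && elem == 0x0010) break
  }
  getUS <- function(key) { t <- tags[[key]]; if (is.null(t)) NULL else u16(t$bytes[1:2]) }
  getStr <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) NULL else trimws(rawToChar(t$bytes[t$bytes != as.raw(0)]))
  }
  frames <- getStr("0028,0008")
  if (!is.null(frames) && as.integer(frames) > 1L)
    eq_error("echoquant_unsupported", "multi-frame DICOM is not supported")
  spp <- getUS("0028,0002")
  if (!is.null(spp) && spp != 1L)
    eq_error("echoquant_unsupported", "only single-sample (grayscale) DICOM is supported")
  bits <- getUS("0028,0100")
  if (is.null(bits) || bits != 8L)
    eq_error("echoquant_unsupported", "only 8-bit DICOM pixel data is supported")
  rows <- getUS("0028,0010"); cols <- getUS("0028,0011")
  pd <- tags[["7FE0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(pd))
    eq_error("echoquant_format", "DICOM file lacks Rows/Columns/PixelData")
  vals <- as.integer(pd$bytes[seq_len(rows * cols)])
  photo <- getStr("0028,0004")
  if (identical(photo, "MONOCHROME1")) vals <- 255L - vals
  gray_image(matrix(vals, nrow = rows, ncol = cols, byrow = TRUE), source = path)
}

raw_u16 <- function(x) as.raw(c(x %% 256L, x %/% 256L))
raw_u32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

dicom_element <- function(group, elem, vr, value_bytes) {
  if (length(value_bytes) %% 2L == 1L)
    value_bytes <- c(value_bytes, if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" "))
  head <- c(raw_u16(group), raw_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), raw_u32(length(value_bytes)), value_bytes)
  } else {
    c(head, raw_u16(length(value_bytes)), value_bytes)
  }
}

#' Write a matrix of gray values as a single-frame 8-bit DICOM file
#'
#' Produces an explicit-VR little-endian part-10 file (secondary-capture SOP
#' class) carrying the matrix as `MONOCHROME2` 8-bit pixel data. Intended
#' for phantoms and test fixtures; [read_dicom_gray] round-trips it exactly.
#'
#' @param pixels integer matrix of gray values in `[0, 255]`.
#' @param path output path.
#' @param photometric `"MONOCHROME2"` (default) or `"MONOCHROME1"` (pixel
#'   values are stored inverted so that the file displays identically).
#' @return `path`, invisibly.
#' @export
write_dicom_gray <- function(pixels, path, photometric = c("MONOCHROME2", "MONOCHROME1")) {
  photometric <- match.arg(photometric)
  if (!is.matrix(pixels) || anyNA(pixels) || any(pixels < 0) || any(pixels > 255))
    eq_error("echoquant_format", "pixels must be a matrix of values in [0, 255]")
  vals <- as.integer(round(pixels))
  if (photometric == "MONOCHROME1") vals <- 255L - vals
  # row-major pixel order
  body_px <- as.raw(as.vector(t(matrix(vals, nrow(pixels), ncol(pixels)))))

  sop_class <- "1.2.840.10008.5.1.4.1.1.7"   # secondary capture
  sop_inst <- "1.2.826.0.1.3680043.8.498.1"  # fixed synthetic instance UID
  meta <- c(
    dicom_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dicom_element(0x0002, 0x0002, "UI", charToRaw(sop_class)),
    dicom_element(0x0002, 0x0003, "UI", charToRaw(sop_inst)),
    dicom_element(0x0002, 0x0010, "UI", charToRaw(DICOM_TS_EXPLICIT_LE))
  )
  meta <- c(dicom_element(0x0002, 0x0000, "UL", raw_u32(length(meta))), meta)
  ds <- c(
    dicom_element(0x0008, 0x0016, "UI", charToRaw(sop_class)),
    dicom_element(0x0008, 0x0018, "UI", charToRaw(sop_inst)),
    dicom_element(0x0028, 0x0002, "US", raw_u16(1L)),
    dicom_element(0x0028, 0x0004, "CS", charToRaw(photometric)),
    dicom_element(0x0028, 0x0010, "US", raw_u16(nrow(pixels))),
    dicom_element(0x0028, 0x0011, "US", raw_u16(ncol(pixels))),
    dicom_element(0x0028, 0x0100, "US", raw_u16(8L)),
    dicom_element(0x0028, 0x0101, "US", raw_u16(8L)),
    dicom_element(0x0028, 0x0102, "US", raw_u16(7L)),
    dicom_element(0x0028, 0x0103, "US", raw_u16(0L)),
    dicom_element(0x7FE0, 0x0010, "OB", body_px)
  )
  out <- c(as.raw(rep(0L, 128L)), charToRaw("DICM"), meta, ds)
  writeBin(out, path)
  invisible(path)
}
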