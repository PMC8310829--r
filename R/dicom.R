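# Minimal single-frame grayscale DICOM support (Explicit VR Little Endian,
# Secondary Capture). Covers exactly what the pipeline exchanges: one 8- or
# 16-bit monochrome (or interleaved RGB) frame plus pixel spacing. Multi-frame
# and compressed transfer syntaxes are rejected.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
SOP_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

# One explicit-VR data element. `value` is raw (already encoded).
.elem <- function(group, element, vr, value) {
  if (length(value) %% 2 == 1) {
    pad <- if (vr %in% c("UI")) as.raw(0) else charToRaw(" ")
    value <- c(value, pad)
  }
  head <- c(.u16(group), .u16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    c(head, as.raw(c(0, 0)), .u32(length(value)), value)
  } else {
    c(head, .u16(length(value)), value)
  }
}

.elem_str <- function(group, element, vr, s) .elem(group, element, vr, charToRaw(s))
.elem_us <- function(group, element, v) .elem(group, element, "US", .u16(v))

.dicom_uid <- function(suffix) paste0("1.2.826.0.1.3680043.9.7426.", suffix)

#' Write a single-frame grayscale DICOM file
#'
#' Encodes an intensity matrix as an uncompressed Explicit VR Little Endian
#' secondary-capture object with `MONOCHROME2` photometric interpretation
#' and 8 bits per pixel. Intensities are clamped to `[0, 255]` and rounded.
#'
#' @param pixels numeric matrix (rows x columns) of intensities in `[0, 255]`.
#' @param path output file path.
#' @param spacing length-2 numeric, physical (row, column) pixel spacing in mm.
#' @param case_id string stored as PatientID/SOP instance suffix.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(pixels, path, spacing = c(1, 1), case_id = "case") {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)), all(spacing > 0))
  px <- round(pmin(pmax(pixels, 0), 255))
  storage.mode(px) <- "integer"
  body <- c(
    .elem_str(0x0008, 0x0016, "UI", SOP_SECONDARY_CAPTURE),
    .elem_str(0x0008, 0x0018, "UI", .dicom_uid(sum(utf8ToInt(case_id)) + 1)),
    .elem_str(0x0008, 0x0060, "CS", "US"),
    .elem_str(0x0010, 0x0010, "PN", case_id),
    .elem_str(0x0010, 0x0020, "LO", case_id),
    .elem_us(0x0028, 0x0002, 1L),                       # SamplesPerPixel
    .elem_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .elem_us(0x0028, 0x0010, nrow(pixels)),             # Rows
    .elem_us(0x0028, 0x0011, ncol(pixels)),             # Columns
    .elem_str(0x0028, 0x0030, "DS",
              sprintf("%.10g\\%.10g", spacing[1], spacing[2])),
    .elem_us(0x0028, 0x0100, 8L),                       # BitsAllocated
    .elem_us(0x0028, 0x0101, 8L),                       # BitsStored
    .elem_us(0x0028, 0x0102, 7L),                       # HighBit
    .elem_us(0x0028, 0x0103, 0L),                       # PixelRepresentation
    .elem(0x7FE0, 0x0010, "OB",
          as.raw(as.vector(t(px))))                     # row-major pixel data
  )
  meta <- c(
    .elem(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .elem_str(0x0002, 0x0002, "UI", SOP_SECONDARY_CAPTURE),
    .elem_str(0x0002, 0x0003, "UI", .dicom_uid(sum(utf8ToInt(case_id)) + 1)),
    .elem_str(0x0002, 0x0010, "UI", TS_EXPLICIT_LE),
    .elem_str(0x0002, 0x0012, "UI", .dicom_uid("1"))
  )
  meta <- c(.elem(0x0002, 0x0000, "UL", .u32(length(meta))), meta)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

# Parse the data-set portion of a DICOM stream into a tag -> raw list.
.parse_dicom_elements <- function(bytes, offset, explicit) {
  n <- length(bytes)
  out <- list()
  i <- offset
  long_vrs <- c("OB", "OW", "OF", "SQ", "UN", "UT")
  while (i + 7 <= n) {
    grp <- readBin(bytes[i:(i + 1)], "integer", size = 2, signed = FALSE,
                   endian = "little")
    ele <- readBin(bytes[(i + 2):(i + 3)], "integer", size = 2, signed = FALSE,
                   endian = "little")
    if (explicit && grp != 0xFFFE) {
      vr <- rawToChar(bytes[(i + 4):(i + 5)])
      if (vr %in% long_vrs) {
        len <- readBin(bytes[(i + 8):(i + 11)], "integer", size = 4,
                       endian = "little")
        i <- i + 12
      } else {
        len <- readBin(bytes[(i + 6):(i + 7)], "integer", size = 2,
                       signed = FALSE, endian = "little")
        i <- i + 8
      }
    } else {
      vr <- "UN"
      len <- readBin(bytes[(i + 4):(i + 7)], "integer", size = 4,
                     endian = "little")
      i <- i + 8
    }
    if (len == -1L) abort("Undefined-length DICOM elements are not supported.")
    if (i + len - 1 > n) break
    key <- sprintf("%04x,%04x", grp, ele)
    out[[key]] <- if (len > 0) bytes[i:(i + len - 1)] else raw(0)
    i <- i + len
  }
  out
}

.dcm_str <- function(el, tag) {
  v <- el[[tag]]
  if (is.null(v)) return(NULL)
  trimws(gsub("\\x00", "", rawToChar(v), useBytes = TRUE))
}

.dcm_us <- function(el, tag) {
  v <- el[[tag]]
  if (is.null(v)) return(NULL)
  readBin(v, "integer", size = 2, signed = FALSE, endian = "little")
}

#' Read a single-frame DICOM file
#'
#' Supports uncompressed Explicit and Implicit VR Little Endian objects with
#' one frame, 8 or 16 bits per sample, monochrome or interleaved RGB (RGB is
#' converted to BT.601 luminance by [read_frame()]).
#'
#' @param path DICOM file path.
#' @return list with `pixels` matrix (per-channel list for RGB), `spacing`,
#'   `photometric`, `case_id`.
#' @export
read_dicom <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 140) abort(sprintf("Not a readable DICOM file: %s", path))
  offset <- 1L
  explicit <- TRUE
  if (rawToChar(bytes[129:132]) == "DICM") {
    meta <- .parse_dicom_elements(bytes, 133L, explicit = TRUE)
    ts <- .dcm_str(meta, "0002,0010")
    # skip preamble + magic + file meta group
    meta_len <- readBin(meta[["0002,0000"]], "integer", size = 4,
                        endian = "little")
    offset <- 133L + 12L + meta_len
    if (!is.null(ts)) {
      if (!ts %in% c(TS_EXPLICIT_LE, TS_IMPLICIT_LE)) {
        abort(sprintf("Unsupported transfer syntax: %s", ts))
      }
      explicit <- ts == TS_EXPLICIT_LE
    }
  }
  el <- .parse_dicom_elements(bytes, offset, explicit = explicit)
  nframes <- .dcm_str(el, "0028,0008")
  if (!is.null(nframes) && as.integer(nframes) > 1L) {
    abort("Multi-frame DICOM objects are not supported.")
  }
  rows <- .dcm_us(el, "0028,0010"); cols <- .dcm_us(el, "0028,0011")
  bits <- .dcm_us(el, "0028,0100") %||% 8L
  spp <- .dcm_us(el, "0028,0002") %||% 1L
  photometric <- .dcm_str(el, "0028,0004") %||% "MONOCHROME2"
  pd <- el[["7fe0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(pd)) {
    abort(sprintf("Missing image elements in DICOM file: %s", path))
  }
  vals <- if (bits <= 8) {
    as.integer(pd)
  } else {
    readBin(pd, "integer", n = length(pd) / 2, size = 2, signed = FALSE,
            endian = "little")
  }
  spacing <- NULL
  sp <- .dcm_str(el, "0028,0030")
  if (!is.null(sp) && nzchar(sp)) {
    spacing <- as.numeric(strsplit(sp, "\\\\")[[1]][1:2])
  }
  case_id <- .dcm_str(el, "0010,0020") %||% NA_character_
  vals <- as.double(vals)
  if (spp == 1L) {
    pixels <- matrix(vals[seq_len(rows * cols)], nrow = rows, byrow = TRUE)
    channels <- NULL
  } else {
    # interleaved (planar configuration 0) colour-by-pixel
    vals <- vals[seq_len(rows * cols * spp)]
    channels <- lapply(seq_len(spp), function(k) {
      matrix(vals[seq(k, length(vals), by = spp)], nrow = rows, byrow = TRUE)
    })
    pixels <- channels[[1]]
  }
  list(pixels = pixels, channels = channels, spacing = spacing,
       photometric = photometric, samples_per_pixel = spp, case_id = case_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
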