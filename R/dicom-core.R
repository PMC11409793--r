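# Minimal DICOM Part-10 codec: uncompressed single-frame little-endian
# files (explicit VR written; explicit and implicit VR read). Only the
# tags this tool needs are in the dictionary; unknown tags are carried
# through as opaque raw payloads. Sequences, undefined lengths and
# compressed transfer syntaxes are out of scope and rejected loudly.

TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CLASS_SC   <- "1.2.840.10008.5.1.4.1.1.7"  # secondary capture storage
IMPL_CLASS_UID <- "2.25.841984310271"

# tag -> (vr, name); tags are "GGGG,EEEE" uppercase hex
.dcm_dict <- local({
  d <- rbind(
    c("0002,0001", "OB", "FileMetaInformationVersion"),
    c("0002,0002", "UI", "MediaStorageSOPClassUID"),
    c("0002,0003", "UI", "MediaStorageSOPInstanceUID"),
    c("0002,0010", "UI", "TransferSyntaxUID"),
    c("0002,0012", "UI", "ImplementationClassUID"),
    c("0008,0008", "CS", "ImageType"),
    c("0008,0016", "UI", "SOPClassUID"),
    c("0008,0018", "UI", "SOPInstanceUID"),
    c("0008,0020", "DA", "StudyDate"),
    c("0008,0030", "TM", "StudyTime"),
    c("0008,0060", "CS", "Modality"),
    c("0008,103E", "LO", "SeriesDescription"),
    c("0010,0010", "PN", "PatientName"),
    c("0010,0020", "LO", "PatientID"),
    c("0018,0050", "DS", "SliceThickness"),
    c("0020,000D", "UI", "StudyInstanceUID"),
    c("0020,000E", "UI", "SeriesInstanceUID"),
    c("0020,0011", "IS", "SeriesNumber"),
    c("0020,0013", "IS", "InstanceNumber"),
    c("0020,0032", "DS", "ImagePositionPatient"),
    c("0020,0037", "DS", "ImageOrientationPatient"),
    c("0028,0002", "US", "SamplesPerPixel"),
    c("0028,0004", "CS", "PhotometricInterpretation"),
    c("0028,0008", "IS", "NumberOfFrames"),
    c("0028,0010", "US", "Rows"),
    c("0028,0011", "US", "Columns"),
    c("0028,0030", "DS", "PixelSpacing"),
    c("0028,0100", "US", "BitsAllocated"),
    c("0028,0101", "US", "BitsStored"),
    c("0028,0102", "US", "HighBit"),
    c("0028,0103", "US", "PixelRepresentation"),
    c("0028,1052", "DS", "RescaleIntercept"),
    c("0028,1053", "DS", "RescaleSlope"),
    c("7FE0,0010", "OW", "PixelData")
  )
  data.frame(tag = d[, 1], vr = d[, 2], name = d[, 3])
})

.dcm_vr_for <- function(tag) {
  i <- match(tag, .dcm_dict$tag)
  if (is.na(i)) "UN" else .dcm_dict$vr[i]
}

.dcm_tag_for_name <- function(name) {
  i <- match(name, .dcm_dict$name)
  if (is.na(i)) stop("unknown DICOM attribute name: ", name, call. = FALSE)
  .dcm_dict$tag[i]
}

.u16 <- function(raw, pos) {
  readBin(raw[pos + 0:1], "integer", n = 1L, size = 2L,
          signed = FALSE, endian = "little")
}
.u32 <- function(raw, pos) {
  # read as double to stay safe for lengths >= 2^31
  lo <- .u16(raw, pos)
  hi <- .u16(raw, pos + 2L)
  hi * 65536 + lo
}

.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Parse one data element starting at pos; returns list(tag, vr, raw, next_pos)
.dcm_parse_element <- function(raw, pos, explicit) {
  grp <- .u16(raw, pos)
  ele <- .u16(raw, pos + 2L)
  tag <- sprintf("%04X,%04X", grp, ele)
  pos <- pos + 4L
  if (explicit) {
    vr <- rawToChar(raw[pos + 0:1])
    if (vr %in% .long_vrs) {
      len <- .u32(raw, pos + 4L)
      pos <- pos + 8L
    } else {
      len <- .u16(raw, pos + 2L)
      pos <- pos + 4L
    }
  } else {
    vr <- .dcm_vr_for(tag)
    len <- .u32(raw, pos)
    pos <- pos + 4L
  }
  if (len >= 4294967295) {
    stop("undefined-length element ", tag, " is not supported", call. = FALSE)
  }
  if (vr == "SQ") {
    stop("sequence element ", tag, " is not supported", call. = FALSE)
  }
  val <- if (len > 0) raw[pos + seq_len(len) - 1L] else raw(0)
  list(tag = tag, vr = vr, raw = val, next_pos = pos + len)
}

#' Read a DICOM Part-10 file
#'
#' Parses an uncompressed single-frame little-endian DICOM file (explicit
#' or implicit VR) into a flat list of data elements keyed by tag.
#'
#' @param path path to a DICOM Part-10 file.
#' @return an object of class `dicom_dataset`: a list with `elements`
#'   (named list of `list(vr, raw)` keyed by `"GGGG,EEEE"`), the
#'   `transfer_syntax` UID and the source `path`.
#' @seealso [dcm_string()], [dcm_numbers()], [dcm_pixels()]
#' @export
dcm_read <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 140) {
    stop("not a DICOM Part-10 file (too short): ", path, call. = FALSE)
  }
  raw <- readBin(path, "raw", n = sz)
  if (rawToChar(raw[129:132]) != "DICM") {
    stop("not a DICOM Part-10 file (missing DICM magic): ", path, call. = FALSE)
  }
  pos <- 133L
  elements <- list()
  # file meta group is always explicit VR little endian
  repeat {
    if (pos > sz) stop("truncated file meta group: ", path, call. = FALSE)
    el <- .dcm_parse_element(raw, pos, explicit = TRUE)
    grp <- substr(el$tag, 1, 4)
    if (grp != "0002") break
    elements[[el$tag]] <- list(vr = el$vr, raw = el$raw)
    pos <- el$next_pos
  }
  ts <- .raw_string(elements[["0002,0010"]]$raw)
  if (is.null(ts) || !nzchar(ts)) ts <- TS_EXPLICIT_LE
  if (!ts %in% c(TS_IMPLICIT_LE, TS_EXPLICIT_LE)) {
    stop("unsupported transfer syntax ", ts,
         " (only uncompressed little endian is supported)", call. = FALSE)
  }
  explicit <- ts == TS_EXPLICIT_LE
  while (pos <= sz - 7L) {
    el <- .dcm_parse_element(raw, pos, explicit = explicit)
    elements[[el$tag]] <- list(vr = el$vr, raw = el$raw)
    pos <- el$next_pos
  }
  structure(list(elements = elements, transfer_syntax = ts, path = path),
            class = "dicom_dataset")
}

.raw_string <- function(r) {
  if (is.null(r) || length(r) == 0) return(NULL)
  r <- r[r != as.raw(0)]
  sub("[ ]+$", "", rawToChar(r))
}

#' @rdname dcm_read
#' @param ds a `dicom_dataset`.
#' @param name a DICOM attribute name from this package's dictionary
#'   (e.g. `"SeriesInstanceUID"`).
#' @export
dcm_string <- function(ds, name) {
  el <- ds$elements[[.dcm_tag_for_name(name)]]
  if (is.null(el)) return(NULL)
  .raw_string(el$raw)
}

#' @rdname dcm_read
#' @export
dcm_numbers <- function(ds, name) {
  tag <- .dcm_tag_for_name(name)
  el <- ds$elements[[tag]]
  if (is.null(el)) return(NULL)
  vr <- .dcm_vr_for(tag)
  if (vr %in% c("DS", "IS")) {
    s <- .raw_string(el$raw)
    if (is.null(s)) return(NULL)
    as.numeric(strsplit(s, "\\\\")[[1]])
  } else if (vr == "US") {
    readBin(el$raw, "integer", n = length(el$raw) %/% 2L, size = 2L,
            signed = FALSE, endian = "little")
  } else {
    stop("attribute ", name, " (VR ", vr, ") is not numeric", call. = FALSE)
  }
}

#' @rdname dcm_read
#' @export
dcm_pixels <- function(ds) {
  el <- ds$elements[[.dcm_tag_for_name("PixelData")]]
  if (is.null(el)) stop("dataset has no PixelData", call. = FALSE)
  rows <- dcm_numbers(ds, "Rows")
  cols <- dcm_numbers(ds, "Columns")
  bits <- dcm_numbers(ds, "BitsAllocated")
  pr <- dcm_numbers(ds, "PixelRepresentation")
  if (is.null(pr)) pr <- 0L
  if (is.null(rows) || is.null(cols) || is.null(bits)) {
    stop("dataset lacks Rows/Columns/BitsAllocated", call. = FALSE)
  }
  n <- rows * cols
  v <- if (bits == 16) {
    readBin(el$raw, "integer", n = n, size = 2L,
            signed = pr == 1L, endian = "little")
  } else if (bits == 8) {
    as.integer(el$raw[seq_len(n)])
  } else {
    stop("unsupported BitsAllocated: ", bits, call. = FALSE)
  }
  # DICOM pixel data is row-major
  matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
}

# ---- writing ----------------------------------------------------------

.pad_even <- function(s, pad) {
  b <- charToRaw(s)
  if (length(b) %% 2L == 1L) b <- c(b, pad)
  b
}

.encode_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.encode_u32 <- function(x) {
  x <- as.numeric(x)
  c(.encode_u16(x %% 65536), .encode_u16(x %/% 65536))
}

# Encode a value for a VR into its raw payload.
.dcm_encode_value <- function(vr, value) {
  if (is.raw(value)) return(value)
  if (vr %in% c("US")) {
    return(writeBin(as.integer(value), raw(), size = 2L, endian = "little"))
  }
  if (vr %in% c("UL")) {
    return(.encode_u32(value))
  }
  if (vr == "DS") {
    s <- paste(vapply(value, function(v) {
      out <- formatC(v, digits = 10, format = "g", flag = "")
      out <- gsub(" ", "", out)
      if (nchar(out) > 16) out <- substr(out, 1, 16)
      out
    }, character(1)), collapse = "\\")
    return(.pad_even(s, charToRaw(" ")))
  }
  if (vr == "IS") {
    return(.pad_even(paste(as.integer(value), collapse = "\\"), charToRaw(" ")))
  }
  if (vr == "UI") {
    return(.pad_even(paste(value, collapse = "\\"), as.raw(0)))
  }
  # text-like VRs
  .pad_even(paste(value, collapse = "\\"), charToRaw(" "))
}

# One explicit-VR-little-endian element as raw bytes.
.dcm_encode_element <- function(tag, vr, payload) {
  grp <- strtoi(substr(tag, 1, 4), 16L)
  ele <- strtoi(substr(tag, 6, 9), 16L)
  head <- c(.encode_u16(grp), .encode_u16(ele), charToRaw(vr))
  if (vr %in% .long_vrs) {
    c(head, as.raw(c(0, 0)), .encode_u32(length(payload)), payload)
  } else {
    if (length(payload) > 65534) {
      stop("element ", tag, " too long for short VR ", vr, call. = FALSE)
    }
    c(head, .encode_u16(length(payload)), payload)
  }
}

# Write a Part-10 explicit-VR-little-endian file. `attrs` is a named list
# (dictionary attribute names -> values); pixels is an integer matrix
# [row, col] written as unsigned 16-bit.
dcm_write <- function(path, attrs, pixels) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix", call. = FALSE)
  stor <- round(pixels)
  storage.mode(stor) <- "integer"
  stor[stor < 0L] <- 0L
  stor[stor > 65535L] <- 65535L

  base <- list(
    ImageType = "DERIVED\\SECONDARY",
    Modality = "MR",
    SamplesPerPixel = 1L,
    PhotometricInterpretation = "MONOCHROME2",
    Rows = nrow(pixels),
    Columns = ncol(pixels),
    BitsAllocated = 16L,
    BitsStored = 16L,
    HighBit = 15L,
    PixelRepresentation = 0L,
    RescaleIntercept = 0,
    RescaleSlope = 1
  )
  base[names(attrs)] <- attrs
  attrs <- base[!vapply(base, is.null, logical(1))]

  tags <- vapply(names(attrs), .dcm_tag_for_name, character(1))
  ord <- order(tags)
  body <- raw(0)
  for (i in ord) {
    vr <- .dcm_vr_for(tags[i])
    body <- c(body, .dcm_encode_element(tags[i], vr, .dcm_encode_value(vr, attrs[[i]])))
  }
  # pixel data: row-major unsigned 16-bit little endian
  px <- as.vector(t(stor))
  px <- px - 65536L * (px > 32767L)  # writeBin size=2 wants signed range
  body <- c(body, .dcm_encode_element("7FE0,0010", "OW",
                                      writeBin(px, raw(), size = 2L, endian = "little")))

  sop_class <- attrs$SOPClassUID %||% SOP_CLASS_SC
  sop_uid <- attrs$SOPInstanceUID %||% dcm_uid()
  meta_el <- c(
    .dcm_encode_element("0002,0001", "OB", as.raw(c(0, 1))),
    .dcm_encode_element("0002,0002", "UI", .dcm_encode_value("UI", sop_class)),
    .dcm_encode_element("0002,0003", "UI", .dcm_encode_value("UI", sop_uid)),
    .dcm_encode_element("0002,0010", "UI", .dcm_encode_value("UI", TS_EXPLICIT_LE)),
    .dcm_encode_element("0002,0012", "UI", .dcm_encode_value("UI", IMPL_CLASS_UID))
  )
  meta <- c(.dcm_encode_element("0002,0000", "UL", .encode_u32(length(meta_el))),
            meta_el)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.uid_env <- new.env(parent = emptyenv())
.uid_env$n <- 0L

#' Generate a fresh DICOM UID
#'
#' UIDs are built from wall-clock time, the process id and an in-process
#' counter, so repeated calls never collide (and re-running a pipeline
#' yields new identifiers, as required for derived DICOM series).
#'
#' @return a character UID under a `2.25.` style numeric root.
#' @export
dcm_uid <- function() {
  .uid_env$n <- .uid_env$n + 1L
  sprintf("2.25.%.0f%05d%06d",
          as.numeric(Sys.time()) * 1000,
          Sys.getpid() %% 100000L,
          .uid_env$n)
}
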