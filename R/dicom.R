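# Minimal DICOM series reader (little-endian, explicit or implicit VR).
#
# Covers what a CT slice series needs: series identity, geometry, rescale to
# HU, and uncompressed 8/16-bit PixelData. Sequences and encapsulated
# transfer syntaxes are rejected up front.

TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

# VRs carrying a 2-byte reserved field and 4-byte length in explicit mode
LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

read_uint16 <- function(raw, at) {
  as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
}

read_uint32 <- function(raw, at) {
  as.numeric(raw[at]) + 256 * as.numeric(raw[at + 1L]) +
    65536 * as.numeric(raw[at + 2L]) + 16777216 * as.numeric(raw[at + 3L])
}

dicom_tag <- function(raw, at) {
  sprintf("%04x%04x", read_uint16(raw, at), read_uint16(raw, at + 2L))
}

# DICOM strings may carry trailing NUL/space padding
dicom_string <- function(bytes) {
  trimws(rawToChar(bytes[bytes != as.raw(0)]))
}

# Parse one DICOM file into a named list of the elements of interest.
parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 132L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L

  wanted <- c(
    "0020000e" = "SeriesInstanceUID",  "00280010" = "Rows",
    "00280011" = "Columns",            "00280030" = "PixelSpacing",
    "00200032" = "ImagePositionPatient",
    "00200037" = "ImageOrientationPatient",
    "00281052" = "RescaleIntercept",   "00281053" = "RescaleSlope",
    "00280100" = "BitsAllocated",      "00280103" = "PixelRepresentation",
    "7fe00010" = "PixelData")
  out <- list()
  ts <- TS_EXPLICIT_LE  # meta group is always explicit LE

  explicit <- TRUE
  in_meta <- TRUE
  while (pos + 7L <= length(raw)) {
    group <- read_uint16(raw, pos)
    if (in_meta && group != 2L) {
      in_meta <- FALSE
      explicit <- identical(ts, TS_EXPLICIT_LE)
    }
    tag <- dicom_tag(raw, pos)
    pos <- pos + 4L
    if (explicit || in_meta) {
      vr <- rawToChar(raw[pos:(pos + 1L)])
      if (vr %in% LONG_VRS) {
        len <- read_uint32(raw, pos + 4L)
        pos <- pos + 8L
      } else {
        len <- read_uint16(raw, pos + 2L)
        pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- read_uint32(raw, pos)
      pos <- pos + 4L
    }
    if (len == 4294967295) stop("undefined-length element (sequence?) unsupported in ", path)
    bytes <- if (len > 0) raw[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len

    if (tag == "00020010")
      ts <- dicom_string(bytes)
    if (!tag %in% names(wanted)) next
    name <- wanted[[tag]]
    out[[name]] <- switch(name,
      SeriesInstanceUID = dicom_string(bytes),
      Rows = ,
      Columns = ,
      BitsAllocated = ,
      PixelRepresentation = read_uint16(bytes, 1L),
      PixelSpacing = ,
      ImagePositionPatient = ,
      ImageOrientationPatient = ,
      RescaleIntercept = ,
      RescaleSlope = as.numeric(strsplit(dicom_string(bytes), "\\\\")[[1]]),
      PixelData = bytes)
  }
  if (!identical(ts, TS_EXPLICIT_LE) && !identical(ts, TS_IMPLICIT_LE))
    stop("unsupported transfer syntax ", ts, " in ", path)
  out
}

dicom_pixel_matrix <- function(el, path) {
  bits <- el$BitsAllocated %||% 16L
  signed <- isTRUE((el$PixelRepresentation %||% 0L) == 1L)
  nr <- el$Rows; nc <- el$Columns
  if (is.null(nr) || is.null(nc) || is.null(el$PixelData))
    stop("missing image geometry or PixelData in ", path)
  if (bits == 16L) {
    v <- readBin(el$PixelData, "integer", n = nr * nc, size = 2L,
                 signed = signed, endian = "little")
    if (!signed) v[v < 0] <- v[v < 0] + 65536L
  } else if (bits == 8L) {
    v <- as.integer(el$PixelData[seq_len(nr * nc)])
  } else stop("unsupported BitsAllocated ", bits, " in ", path)
  # PixelData is row-major: index (column-fastest) -> [col, row] matrix
  matrix(v, nrow = nc, ncol = nr)
}

load_dicom_series <- function(path) {
  files <- sort(list.files(path, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM directory ", path)
  parsed <- lapply(files, parse_dicom_file)

  uids <- vapply(parsed, function(e) e$SeriesInstanceUID %||% NA_character_,
                 character(1))
  if (length(unique(uids)) > 1L)
    stop("mixed DICOM series in ", path, ": ",
         paste(unique(uids), collapse = ", "))

  for (i in seq_along(parsed)) {
    e <- parsed[[i]]
    if (is.null(e$RescaleSlope) || is.null(e$RescaleIntercept))
      stop("missing RescaleSlope/RescaleIntercept in ", files[i])
    if (is.null(e$ImagePositionPatient) || is.null(e$ImageOrientationPatient))
      stop("missing position/orientation tags in ", files[i])
  }

  iop <- parsed[[1]]$ImageOrientationPatient
  row_dir <- iop[1:3]   # direction of increasing column index
  col_dir <- iop[4:6]   # direction of increasing row index
  normal <- cross3(row_dir, col_dir)

  # sort slices along the normal, not by InstanceNumber
  proj <- vapply(parsed, function(e) sum(e$ImagePositionPatient * normal),
                 numeric(1))
  ord <- order(proj)
  parsed <- parsed[ord]
  proj <- proj[ord]

  ps <- parsed[[1]]$PixelSpacing  # (row spacing, column spacing)
  nslices <- length(parsed)
  slices <- lapply(seq_len(nslices), function(i) {
    e <- parsed[[i]]
    dicom_pixel_matrix(e, files[i]) * e$RescaleSlope[1] + e$RescaleIntercept[1]
  })
  nc <- nrow(slices[[1]]); nr <- ncol(slices[[1]])
  vox <- array(0, c(nc, nr, nslices))
  for (i in seq_len(nslices)) vox[, , i] <- slices[[i]]

  ipp0 <- parsed[[1]]$ImagePositionPatient
  if (nslices > 1L) {
    kstep <- (parsed[[nslices]]$ImagePositionPatient - ipp0) / (nslices - 1)
  } else {
    kstep <- normal  # 1 mm nominal slice step for single-slice input
  }
  affine <- diag(4)
  affine[1:3, 1] <- row_dir * ps[2]
  affine[1:3, 2] <- col_dir * ps[1]
  affine[1:3, 3] <- kstep
  affine[1:3, 4] <- ipp0
  ct_volume(vox, affine)
}
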