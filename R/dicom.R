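# Minimal DICOM support: Part-10 files, explicit VR little endian, classic
# single-frame MR images, 16-bit unsigned pixel data. This covers exactly
# what the QC pipeline needs (PixelSpacing, InstanceNumber,
# SeriesInstanceUID, AcquisitionTime, MagneticFieldStrength,
# RescaleSlope/Intercept, PixelData); it is not a general DICOM toolkit.

TRANSFER_SYNTAX_ELE <- "1.2.840.10008.1.2.1"
SOP_CLASS_MR <- "1.2.840.10008.5.1.4.1.1.4"
UID_ROOT <- "1.2.826.0.1.3680043.9.7433"

u16le <- function(x) as.raw(c(x %% 256L, (x %/% 256L) %% 256L))
u32le <- function(x) {
  x <- as.double(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

padEven <- function(raw, pad) {
  if (length(raw) %% 2L == 1L) c(raw, pad) else raw
}

# One data element in explicit VR little endian.
dcmElement <- function(group, elem, vr, value) {
  val <- if (is.raw(value)) value else charToRaw(as.character(value))
  val <- padEven(val, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  hdr <- c(u16le(group), u16le(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, as.raw(c(0L, 0L)), u32le(length(val)), val)
  } else {
    c(hdr, u16le(length(val)), val)
  }
}

dcmUS <- function(group, elem, x) dcmElement(group, elem, "US", u16le(x))

fmtDS <- function(x) {
  s <- formatC(x, digits = 10, format = "g")
  paste(trimws(s), collapse = "\\")
}

secondsToTM <- function(t) {
  h <- floor(t / 3600); m <- floor((t - 3600 * h) / 60); s <- t - 3600 * h - 60 * m
  sprintf("%02d%02d%09.6f", h, m, s)
}

tmToSeconds <- function(tm) {
  tm <- trimws(tm)
  h <- as.numeric(substr(tm, 1, 2)); m <- as.numeric(substr(tm, 3, 4))
  s <- as.numeric(substring(tm, 5))
  3600 * h + 60 * m + s
}

makeUid <- function(seed) {
  paste0(UID_ROOT, ".", abs(seed) %% 1e9, ".",
         sample.int(.Machine$integer.max, 1))
}

pixelsToRaw <- function(stored) {
  v <- as.vector(t(stored))  # DICOM pixel data is row-major
  as.raw(rbind(v %% 256L, v %/% 256L))
}

#' Write one slice as a DICOM file
#'
#' Intensities are rounded to the nearest integer and stored as 16-bit
#' unsigned pixel data (as real scanners store them); values must fall in
#' [0, 65535] after rounding. \code{RescaleSlope = 1},
#' \code{RescaleIntercept = 0} are recorded explicitly.
#'
#' @param slice an [AcquisitionSlice-class].
#' @param path output file path.
#' @param seriesUid SeriesInstanceUID string shared by the series.
#' @param instanceNumber DICOM InstanceNumber (defaults to the slice index).
#' @return \code{path}, invisibly.
#' @export
writeDicomSlice <- function(slice, path, seriesUid,
                            instanceNumber = sliceIndex(slice)) {
  stored <- round(slice@pixels)
  if (any(stored < 0) || any(stored > 65535))
    stopQc("io", "pixel intensities outside the 16-bit unsigned range")
  sopUid <- paste0(seriesUid, ".", as.integer(instanceNumber))

  meta <- c(
    dcmElement(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcmElement(0x0002, 0x0002, "UI", SOP_CLASS_MR),
    dcmElement(0x0002, 0x0003, "UI", sopUid),
    dcmElement(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_ELE),
    dcmElement(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".1"))
  )
  body <- c(
    dcmElement(0x0008, 0x0016, "UI", SOP_CLASS_MR),
    dcmElement(0x0008, 0x0018, "UI", sopUid),
    dcmElement(0x0008, 0x0032, "TM", secondsToTM(slice@acquisitionTime)),
    dcmElement(0x0008, 0x0060, "CS", "MR"),
    dcmElement(0x0018, 0x0087, "DS", fmtDS(slice@fieldStrengthT)),
    dcmElement(0x0020, 0x000E, "UI", seriesUid),
    dcmElement(0x0020, 0x0013, "IS", as.character(as.integer(instanceNumber))),
    dcmUS(0x0028, 0x0002, 1L),
    dcmElement(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcmUS(0x0028, 0x0010, nrow(stored)),
    dcmUS(0x0028, 0x0011, ncol(stored)),
    dcmElement(0x0028, 0x0030, "DS", fmtDS(c(slice@py, slice@px))),
    dcmUS(0x0028, 0x0100, 16L),
    dcmUS(0x0028, 0x0101, 16L),
    dcmUS(0x0028, 0x0102, 15L),
    dcmUS(0x0028, 0x0103, 0L),
    dcmElement(0x0028, 0x1052, "DS", "0"),
    dcmElement(0x0028, 0x1053, "DS", "1"),
    dcmElement(0x7FE0, 0x0010, "OW", pixelsToRaw(stored))
  )
  groupLen <- dcmElement(0x0002, 0x0000, "UL", u32le(length(meta)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(rep(0L, 128)), charToRaw("DICM"), groupLen, meta, body),
           con)
  invisible(path)
}

#' Write a series of slices as DICOM files
#'
#' @param slices list of [AcquisitionSlice-class].
#' @param dir output directory (created if needed).
#' @param seriesUid optional SeriesInstanceUID; generated when missing.
#' @return character vector of written paths, invisibly.
#' @export
writeDicomSeries <- function(slices, dir, seriesUid = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(seriesUid))
    seriesUid <- withSeed(deriveSeed(length(slices), 42L), makeUid(1L))
  paths <- vapply(seq_along(slices), function(i) {
    p <- file.path(dir, sprintf("slice_%03d.dcm", i))
    writeDicomSlice(slices[[i]], p, seriesUid, instanceNumber = i)
    p
  }, character(1))
  invisible(paths)
}

readU16 <- function(raw, at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
readU32 <- function(raw, at) {
  sum(as.double(as.integer(raw[at + 0:3])) * c(1, 256, 65536, 16777216))
}

#' Read one DICOM file (explicit VR little endian, single frame)
#'
#' @param path file path.
#' @return named list of the parsed attributes plus the stored pixel matrix
#'   (rescale not yet applied).
#' @export
readDicomFile <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stopQc("io", "not a DICOM Part-10 file: ", path)
  pos <- 133L
  out <- list()
  longVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(raw)) {
    group <- readU16(raw, pos); elem <- readU16(raw, pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% longVRs) {
      len <- readU32(raw, pos + 8L); valAt <- pos + 12L
    } else {
      len <- readU16(raw, pos + 6L); valAt <- pos + 8L
    }
    val <- if (len > 0) raw[valAt:(valAt + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, elem)
    out[[key]] <- switch(vr,
      US = readU16(val, 1L),
      UL = readU32(val, 1L),
      OW = val,
      OB = val,
      trimws(rawToChar(val[val != as.raw(0L)]))
    )
    pos <- valAt + len
    if (group == 0x7FE0 && elem == 0x0010) break
  }
  rows <- out[["0028,0010"]]; cols <- out[["0028,0011"]]
  if (is.null(rows) || is.null(cols))
    stopQc("io", "missing Rows/Columns in ", path)
  pd <- out[["7FE0,0010"]]
  if (is.null(pd) || length(pd) != 2 * rows * cols)
    stopQc("io", "missing or truncated pixel data in ", path)
  idx <- seq(1L, length(pd), by = 2L)
  v <- as.integer(pd[idx]) + 256L * as.integer(pd[idx + 1L])
  spacing <- out[["0028,0030"]]
  list(
    pixels = matrix(v, nrow = rows, byrow = TRUE),
    rows = rows, cols = cols,
    pixelSpacing = if (is.null(spacing)) NULL
                   else as.numeric(strsplit(spacing, "\\\\")[[1]]),
    rescaleSlope = as.numeric(out[["0028,1053"]] %||% "1"),
    rescaleIntercept = as.numeric(out[["0028,1052"]] %||% "0"),
    instanceNumber = as.integer(out[["0020,0013"]] %||% NA),
    seriesUid = out[["0020,000E"]],
    acquisitionTime = if (is.null(out[["0008,0032"]])) NA_real_
                      else tmToSeconds(out[["0008,0032"]]),
    fieldStrengthT = as.numeric(out[["0018,0087"]] %||% NA),
    sourceId = basename(path)
  )
}
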