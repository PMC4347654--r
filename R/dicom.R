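## Minimal DICOM series support: explicit-VR little-endian, uncompressed,
## one single-frame file per slice, unsigned 16-bit pixels. Written by hand
## because the pipeline only needs geometry-faithful slice I/O (no installed
## R package reads DICOM in this package's dependency set); it is not a
## general DICOM implementation.

.dcmUint16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.dcmUint32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.dcmPadStr <- function(s, pad = as.raw(0x20)) {
  b <- charToRaw(s)
  if (length(b) %% 2L) b <- c(b, pad)
  b
}

.dcmElement <- function(group, elem, vr, value) {
  head <- c(.dcmUint16(group), .dcmUint16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), .dcmUint32(length(value)), value)
  } else {
    c(head, .dcmUint16(length(value)), value)
  }
}

#' Write an ImageStack as a DICOM series
#'
#' One explicit-VR little-endian single-frame file per slice
#' (`slice_###.dcm`), unsigned 16-bit pixels, with rows/columns, pixel
#' spacing, slice thickness, spacing between slices, orientation and
#' instance number populated. Signal intensities must be non-negative
#' integers below 65536 (DICOM 16-bit storage).
#'
#' @param stack an [ImageStack-class] with integer-valued voxels.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDicomSeries <- function(stack, dir) {
  stopifnot(is(stack, "ImageStack"))
  v <- voxels(stack)
  if (any(v < 0) || any(v > 65535) || any(v != round(v)))
    stop("DICOM writer stores unsigned 16-bit integers; rescale the stack first")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- pixelSpacing(stack)
  d <- dim(v)
  meta_ts <- .dcmElement(0x0002, 0x0010, "UI", .dcmPadStr("1.2.840.10008.1.2.1", as.raw(0)))
  meta_len <- .dcmElement(0x0002, 0x0000, "UL", .dcmUint32(length(meta_ts)))
  for (s in seq_len(d[3])) {
    px <- as.integer(t(v[, , s]))  # DICOM pixel order is row-major
    body <- c(
      .dcmElement(0x0008, 0x0060, "CS", .dcmPadStr("MR")),
      .dcmElement(0x0008, 0x103E, "LO", .dcmPadStr(modality(stack))),
      .dcmElement(0x0018, 0x0050, "DS", .dcmPadStr(format(sliceThickness(stack)))),
      .dcmElement(0x0018, 0x0088, "DS",
                  .dcmPadStr(format(sliceThickness(stack) + sliceGap(stack)))),
      .dcmElement(0x0020, 0x0013, "IS", .dcmPadStr(format(s))),
      .dcmElement(0x0020, 0x0037, "DS", .dcmPadStr("1\\0\\0\\0\\1\\0")),
      .dcmElement(0x0028, 0x0010, "US", .dcmUint16(d[1])),
      .dcmElement(0x0028, 0x0011, "US", .dcmUint16(d[2])),
      .dcmElement(0x0028, 0x0030, "DS",
                  .dcmPadStr(paste(format(sp[1]), format(sp[2]), sep = "\\"))),
      .dcmElement(0x0028, 0x0100, "US", .dcmUint16(16L)),
      .dcmElement(0x0028, 0x0103, "US", .dcmUint16(0L)),
      .dcmElement(0x7FE0, 0x0010, "OW",
                  writeBin(px, raw(), size = 2, endian = "little"))
    )
    out <- c(raw(128), charToRaw("DICM"), meta_len, meta_ts, body)
    writeBin(out, file.path(dir, sprintf("slice_%03d.dcm", s)))
  }
  invisible(dir)
}

## Parse one minimal DICOM file into a named list of decoded elements.
.readDicomFile <- function(path) {
  bytes <- readBin(path, raw(), file.size(path))
  if (length(bytes) < 132L || rawToChar(bytes[129:132]) != "DICM")
    stop(path, ": not a DICOM file (missing DICM marker)")
  con <- rawConnection(bytes[-(1:132)])
  on.exit(close(con))
  u16 <- function() readBin(con, "integer", size = 2, signed = FALSE, endian = "little")
  u32 <- function() readBin(con, "integer", size = 4, endian = "little")
  out <- list()
  repeat {
    group <- u16()
    if (!length(group)) break
    elem <- u16()
    vr <- rawToChar(readBin(con, raw(), 2))
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      readBin(con, raw(), 2)
      len <- u32()
    } else {
      len <- u16()
    }
    val <- readBin(con, raw(), len)
    tag <- sprintf("%04X,%04X", group, elem)
    out[[tag]] <- switch(vr,
      US = readBin(val, "integer", n = len / 2, size = 2, signed = FALSE,
                   endian = "little"),
      UL = readBin(val, "integer", n = len / 4, size = 4, endian = "little"),
      OW = readBin(val, "integer", n = len / 2, size = 2, signed = FALSE,
                   endian = "little"),
      trimws(rawToChar(val)))
  }
  out
}

#' Read a DICOM series directory
#'
#' Reads every `*.dcm` file in `dir`, orders slices by instance number
#' (base to apex) and checks that all slices share rows, columns, pixel
#' spacing and image orientation; any mismatch (e.g. one rotated slice) is a
#' format error. Missing pixel spacing is an explicit error. The inter-slice
#' gap is recovered as spacing-between-slices minus slice thickness.
#'
#' @param dir directory containing the series.
#' @return an [ImageStack-class].
#' @export
readDicomSeries <- function(dir) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) < 2L) stop("DICOM series needs >= 2 slice files in ", dir)
  parsed <- lapply(files, .readDicomFile)
  need <- function(p, tag, what, f) {
    if (is.null(p[[tag]])) stop(f, ": missing ", what, "; refusing to guess")
    p[[tag]]
  }
  inst <- vapply(seq_along(parsed), function(i)
    as.integer(need(parsed[[i]], "0020,0013", "instance number", files[i])), integer(1))
  ord <- order(inst)
  parsed <- parsed[ord]; files <- files[ord]
  ref <- parsed[[1]]
  spacing <- as.numeric(strsplit(need(ref, "0028,0030", "pixel spacing", files[1]),
                                 "\\\\")[[1]])
  orient <- need(ref, "0020,0037", "image orientation", files[1])
  nr <- need(ref, "0028,0010", "rows", files[1])
  nc <- need(ref, "0028,0011", "columns", files[1])
  for (i in seq_along(parsed)) {
    p <- parsed[[i]]
    if (!identical(p[["0028,0010"]], nr) || !identical(p[["0028,0011"]], nc) ||
        !identical(p[["0028,0030"]], ref[["0028,0030"]]) ||
        !identical(p[["0020,0037"]], orient))
      stop("inconsistent series geometry (slice ", files[i],
           " differs in size, spacing or orientation)")
  }
  thick <- as.numeric(need(ref, "0018,0050", "slice thickness", files[1]))
  between <- if (is.null(ref[["0018,0088"]])) thick else as.numeric(ref[["0018,0088"]])
  if (between < thick)
    stop("spacing between slices smaller than slice thickness")
  v <- array(0, c(nr, nc, length(parsed)))
  for (i in seq_along(parsed)) {
    px <- need(parsed[[i]], "7FE0,0010", "pixel data", files[i])
    v[, , i] <- matrix(px, nrow = nr, byrow = TRUE)
  }
  mod <- ref[["0008,103E"]]
  if (is.null(mod) || !mod %in% c("LGE", "T2w")) mod <- "LGE"
  imageStack(v, spacing, thick, between - thick, modality = mod)
}
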