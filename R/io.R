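## Readers/writers for the formats the pipeline touches: NIfTI stacks (with a
## JSON sidecar for the thickness/gap split and modality metadata), a
## purpose-defined JSON contour format, and long-format CSV ratings tables.

.sidecarPath <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Write an ImageStack as NIfTI (plus JSON sidecar)
#'
#' The voxel array and in-plane spacing go into the NIfTI header (the third
#' pixdim is thickness + gap, i.e. the slice-centre spacing); modality, the
#' thickness/gap split and the optional quality grade go into a JSON sidecar
#' next to the image, since NIfTI has no native fields for them.
#'
#' @param stack an [ImageStack-class].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  img <- RNifti::asNifti(voxels(stack))
  RNifti::pixdim(img) <- c(pixelSpacing(stack),
                           sliceThickness(stack) + sliceGap(stack))
  RNifti::writeNifti(img, path)
  meta <- list(modality = modality(stack),
               pixel_spacing_mm = pixelSpacing(stack),
               slice_thickness_mm = sliceThickness(stack),
               slice_gap_mm = sliceGap(stack))
  if (!is.na(stack@qualityGrade)) meta$quality_grade <- stack@qualityGrade
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ImageStack
#'
#' `format = "nifti"` reads a NIfTI volume (and its JSON sidecar when
#' present; otherwise the third pixdim is taken as slice thickness with zero
#' gap). `format = "dicom"` reads a directory holding one explicit-VR
#' little-endian DICOM file per slice (see [readDicomSeries()]). Slice order
#' is base to apex; signal intensities are taken as stored (no rescaling
#' beyond what the format mandates). Missing spacing is an error, never a
#' silent default.
#'
#' @param path file path (NIfTI) or directory (DICOM series).
#' @param format `"nifti"` or `"dicom"`.
#' @return an [ImageStack-class].
#' @export
readStack <- function(path, format = c("nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "dicom") return(readDicomSeries(path))
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    stop("NIfTI header lacks positive voxel spacing; refusing to guess")
  v <- array(as.numeric(img), dim(img))
  side <- .sidecarPath(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    imageStack(v, unlist(meta$pixel_spacing_mm), meta$slice_thickness_mm,
               meta$slice_gap_mm,
               modality = if (is.null(meta$modality)) "LGE" else meta$modality,
               qualityGrade = if (is.null(meta$quality_grade) ||
                                  !length(meta$quality_grade)) NA_integer_
                              else as.integer(meta$quality_grade))
  } else {
    imageStack(v, pd[1:2], pd[3], 0)
  }
}

#' Write / read contours as JSON
#'
#' The contour format is a small purpose-defined JSON schema: a `slices`
#' array of `{slice, endo, epi}` objects whose polygons are lists of
#' `[row, col]` vertices in 1-based pixel-centred coordinates, slice 1 most
#' basal, implicitly closed. Every contoured slice must carry both polygons
#' (myocardium is undefined otherwise). A self-intersecting polygon is kept,
#' with a warning.
#'
#' @param contours a [ContourSet-class].
#' @param path JSON file path.
#' @return `writeContours`: `path` invisibly; `readContours`: a
#'   [ContourSet-class].
#' @export
writeContours <- function(contours, path) {
  stopifnot(is(contours, "ContourSet"))
  payload <- list(
    coordinates = "1-based pixel-centred [row, col]; slice 1 most basal",
    slices = lapply(contours@contours, function(e)
      list(slice = e$slice, endo = unname(e$endo), epi = unname(e$epi)))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeContours
#' @export
readContours <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- payload$slices
  if (is.null(raw) || (is.data.frame(raw) && !nrow(raw)) || !length(raw))
    return(contourSet(list()))
  get_entry <- function(i) {
    if (is.data.frame(raw)) list(slice = raw$slice[i],
                                 endo = raw$endo[[i]], epi = raw$epi[[i]])
    else raw[[i]]
  }
  n <- if (is.data.frame(raw)) nrow(raw) else length(raw)
  entries <- lapply(seq_len(n), function(i) {
    e <- get_entry(i)
    if (is.null(e$epi) || !length(e$epi))
      stop(sprintf("slice %s: epicardial contour missing (myocardium undefined)", e$slice))
    if (is.null(e$endo) || !length(e$endo))
      stop(sprintf("slice %s: endocardial contour missing (myocardium undefined)", e$slice))
    tidy <- function(p) {
      p <- matrix(as.numeric(unlist(p)), ncol = 2,
                  byrow = !is.matrix(p) && !is.data.frame(p))
      if (is.data.frame(p)) p <- as.matrix(p)
      # drop an explicit closing vertex
      if (nrow(p) > 1L && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
      unname(p)
    }
    endo <- if (is.matrix(e$endo)) unname(e$endo) else tidy(e$endo)
    epi <- if (is.matrix(e$epi)) unname(e$epi) else tidy(e$epi)
    if (nrow(endo) > 1L && all(endo[1, ] == endo[nrow(endo), ]))
      endo <- endo[-nrow(endo), , drop = FALSE]
    if (nrow(epi) > 1L && all(epi[1, ] == epi[nrow(epi), ]))
      epi <- epi[-nrow(epi), , drop = FALSE]
    list(slice = as.integer(e$slice), endo = endo, epi = epi)
  })
  contourSet(entries)
}

## ---- ratings tables --------------------------------------------------------

.ratingsCols <- c("subject", "field_strength", "measure", "method",
                  "rater", "replicate", "value")

## Validate a long-format ratings data frame (shared by reader and pipeline).
.asRatingsTable <- function(df, source = "ratings table") {
  missing_cols <- setdiff(.ratingsCols, names(df))
  if (length(missing_cols))
    stop(source, ": missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[, .ratingsCols]
  bad <- which(!is.finite(df$value))
  if (length(bad))
    stop(source, ": non-numeric or missing value in row(s) ",
         paste(bad, collapse = ", "))
  if (any(df$value < 0 | df$value > 100))
    stop(source, ": values must be within [0, 100] %LVM")
  if (!all(df$measure %in% c("IS", "AAR")))
    stop(source, ": measure must be 'IS' or 'AAR'")
  key <- do.call(paste, c(df[c("subject", "field_strength", "measure", "method",
                               "rater", "replicate")], sep = "\r"))
  if (anyDuplicated(key))
    stop(source, ": duplicate (subject, measure, method, rater, replicate) key")
  df$replicate <- as.integer(df$replicate)
  rownames(df) <- NULL
  df
}

#' Read / write long-format ratings tables
#'
#' Ratings tables are long-format CSV with columns `subject`,
#' `field_strength`, `measure` (IS/AAR), `method`, `rater`, `replicate`,
#' `value` (%LVM, 0-100). A `mapping` (named character vector,
#' `standard_name = "file column"`) lets differently named external tables be
#' ingested without code changes. Non-numeric values are row-level errors;
#' duplicate keys are rejected.
#'
#' @param path CSV file path.
#' @param mapping optional named character vector renaming file columns onto
#'   the standard names.
#' @param ratings a ratings data frame (e.g. from [sampleObserverTable()]).
#' @return `readRatings`: a validated ratings data frame; `writeRatings`:
#'   `path` invisibly.
#' @export
readRatings <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (std in names(mapping)) {
      if (!mapping[[std]] %in% names(df))
        stop("mapped column '", mapping[[std]], "' not present in ", path)
      names(df)[names(df) == mapping[[std]]] <- std
    }
  }
  # row-level numeric check with file line numbers (header = line 1)
  suppressWarnings(num <- as.numeric(df$value))
  bad <- which(is.na(num) & !is.na(df$value))
  if (length(bad))
    stop(sprintf("%s: non-numeric value on line(s) %s", path,
                 paste(bad + 1L, collapse = ", ")))
  df$value <- num
  .asRatingsTable(df, source = path)
}

#' @rdname readRatings
#' @export
writeRatings <- function(ratings, path) {
  ratings <- .asRatingsTable(ratings)
  utils::write.csv(ratings, path, row.names = FALSE)
  invisible(path)
}
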