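#' Construct an ImageStack
#'
#' @param voxels numeric 3-D array `[row, col, slice]`, slice 1 most basal.
#' @param pixelSpacing length-1 or length-2 in-plane spacing in mm.
#' @param sliceThickness slice thickness in mm.
#' @param sliceGap inter-slice gap in mm.
#' @param modality `"LGE"` or `"T2w"`.
#' @param qualityGrade optional integer 0-3 (metadata only).
#' @return an [ImageStack-class].
#' @export
imageStack <- function(voxels, pixelSpacing, sliceThickness, sliceGap = 0,
                       modality = c("LGE", "T2w"), qualityGrade = NA_integer_) {
  modality <- match.arg(modality)
  if (length(pixelSpacing) == 1L) pixelSpacing <- rep(pixelSpacing, 2L)
  new("ImageStack", voxels = voxels, pixelSpacing = as.numeric(pixelSpacing),
      sliceThickness = as.numeric(sliceThickness), sliceGap = as.numeric(sliceGap),
      modality = modality, qualityGrade = as.integer(qualityGrade))
}

#' Construct a ContourSet
#'
#' @param entries list of `list(slice =, endo =, epi =)` entries; `endo`/`epi`
#'   are 2-column `[row, col]` vertex matrices (1-based, pixel-centred,
#'   implicitly closed).
#' @return a [ContourSet-class].
#' @export
contourSet <- function(entries = list()) {
  for (e in entries) {
    for (role in c("endo", "epi")) {
      if (.polygonSelfIntersects(e[[role]]))
        warning(sprintf("%s contour on slice %s self-intersects; keeping it as drawn",
                        role, e$slice))
    }
  }
  new("ContourSet", contours = entries)
}

## Rasterise one slice: voxel centre inside epi polygon and outside endo.
.rasterizeSlicePolys <- function(endo, epi, nr, nc) {
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  in_epi <- .pointsInPolygon(cols, rows, epi[, 2], epi[, 1])
  sl <- matrix(FALSE, nr, nc)
  idx <- which(in_epi)
  if (length(idx)) {
    in_endo <- .pointsInPolygon(cols[idx], rows[idx], endo[, 2], endo[, 1])
    sl[cbind(rows[idx][!in_endo], cols[idx][!in_endo])] <- TRUE
  }
  sl
}

#' Rasterise contours into a myocardial mask
#'
#' A voxel is myocardial iff its centre lies inside the epicardial polygon
#' and outside the endocardial polygon of its slice. Papillary muscles,
#' trabeculae and blood-pool artefact are excluded upstream by how the
#' contours are drawn; this function only encodes the annular region between
#' the two polygons. Identical consecutive contours are rasterised once.
#'
#' @param contours a [ContourSet-class].
#' @param stack the [ImageStack-class] defining the voxel grid.
#' @return a [MyoMask-class] with all contoured slices quantifiable
#'   (apical exclusion is a separate, explicit step,
#'   [excludeApicalSlice()]).
#' @export
rasterizeContours <- function(contours, stack) {
  stopifnot(is(contours, "ContourSet"), is(stack, "ImageStack"))
  d <- dim(voxels(stack))
  mask <- array(FALSE, d)
  contoured <- logical(d[3])
  prev <- NULL
  prev_slice <- NULL
  for (entry in contours@contours) {
    s <- as.integer(entry$slice)
    if (s < 1L || s > d[3])
      stop(sprintf("contoured slice %d outside the stack (1..%d)", s, d[3]))
    endo <- entry$endo; epi <- entry$epi
    contoured[s] <- TRUE
    if (isTRUE(all.equal(endo, epi, check.attributes = FALSE))) {
      warning(sprintf("endo and epi coincide on slice %d; empty myocardium", s))
      next
    }
    inside <- .pointsInPolygon(endo[, 2], endo[, 1], epi[, 2], epi[, 1])
    if (!all(inside))
      stop(sprintf("endocardial contour not inside epicardial contour on slice %d", s))
    if (!is.null(prev) && identical(prev$endo, endo) && identical(prev$epi, epi)) {
      mask[, , s] <- mask[, , prev_slice]
    } else {
      mask[, , s] <- .rasterizeSlicePolys(endo, epi, d[1], d[2])
    }
    prev <- list(endo = endo, epi = epi)
    prev_slice <- s
  }
  new("MyoMask", mask = mask, contoured = contoured,
      excludedApical = logical(d[3]))
}

#' Left-ventricular mass of a myocardial mask
#'
#' `mass = voxel count x pixel area x (thickness + gap) x density`. The
#' density default of 1.05 g/mL is the usual myocardial value; %LVM results
#' do not depend on it because it cancels in the ratio.
#'
#' @param mask a [MyoMask-class].
#' @param stack the matching [ImageStack-class] (geometry source).
#' @param density myocardial density in g/mL.
#' @param slices which slices contribute: `"quantifiable"` (default),
#'   `"contoured"`, or `"all"`.
#' @return mass in grams.
#' @export
lvMass <- function(mask, stack, density = 1.05,
                   slices = c("quantifiable", "contoured", "all")) {
  slices <- match.arg(slices)
  sl <- switch(slices,
    quantifiable = quantifiableSlices(mask),
    contoured = contouredSlices(mask),
    all = seq_len(nSlices(mask)))
  nvox <- sum(mask@mask[, , sl, drop = FALSE])
  if (nvox == 0L) stop("empty myocardial mask: mass undefined")
  .voxelMassG(nvox, stack, density)
}

.voxelMassG <- function(nvox, stack, density = 1.05) {
  sp <- pixelSpacing(stack)
  vol_mm3 <- nvox * sp[1] * sp[2] * (sliceThickness(stack) + sliceGap(stack))
  vol_mm3 / 1000 * density
}

#' Build a fixed-area ROI of nearest myocardial voxels
#'
#' Deterministic stand-in for freehand ROI drawing: the seed point is snapped
#' to its voxel, and the ROI is the N myocardial voxels on that slice nearest
#' to it (Euclidean distance in mm; ties broken by row then column), with
#' `N = round(targetAreaCm2 / pixel area)`. Because the seed snaps to the
#' voxel grid, perturbing it by less than half a pixel cannot change the ROI.
#' The default area of 2 cm^2 is the conventional remote/core ROI size.
#'
#' @param mask a [MyoMask-class].
#' @param stack the matching [ImageStack-class].
#' @param slice slice index.
#' @param seed numeric `c(row, col)` seed point (may be fractional).
#' @param targetAreaCm2 target ROI area in cm^2.
#' @param kind `"remote"` or `"infarct-core"`.
#' @return an [Roi-class].
#' @export
buildRoi <- function(mask, stack, slice, seed, targetAreaCm2 = 2,
                     kind = c("remote", "infarct-core")) {
  kind <- match.arg(kind)
  slice <- as.integer(slice)
  seed <- round(as.numeric(seed))
  d <- dim(mask@mask)
  if (slice < 1L || slice > d[3]) stop("slice index out of range")
  if (seed[1] < 1 || seed[1] > d[1] || seed[2] < 1 || seed[2] > d[2] ||
      !mask@mask[seed[1], seed[2], slice])
    stop("ROI seed point is not myocardial on that slice")
  sp <- pixelSpacing(stack)
  n_target <- round(targetAreaCm2 * 100 / (sp[1] * sp[2]))
  myo <- which(mask@mask[, , slice])
  if (length(myo) < n_target)
    stop(sprintf("myocardial area on slice %d (%d voxels) below the %d-voxel ROI target",
                 slice, length(myo), n_target))
  rc <- arrayInd(myo, d[1:2])
  dist <- sqrt(((rc[, 1] - seed[1]) * sp[1])^2 + ((rc[, 2] - seed[2]) * sp[2])^2)
  ord <- order(dist, rc[, 1], rc[, 2])
  sel <- rc[ord[seq_len(n_target)], , drop = FALSE]
  colnames(sel) <- c("row", "col")
  new("Roi", slice = slice, voxels = sel,
      targetAreaCm2 = as.numeric(targetAreaCm2), kind = kind)
}

#' Exclude the most apical slice from quantification
#'
#' Flags the most apical contoured slice as excluded to minimise partial
#' volume effects. Under the default mass convention the excluded slice
#' contributes neither enhancement nor mass to %LVM (it drops out of both
#' numerator and denominator). Idempotent: if an apical exclusion flag is
#' already set the mask is returned unchanged.
#'
#' @param mask a [MyoMask-class] with >= 2 contoured slices.
#' @return the flagged [MyoMask-class].
#' @export
excludeApicalSlice <- function(mask) {
  stopifnot(is(mask, "MyoMask"))
  if (any(mask@excludedApical)) return(mask)
  cont <- which(mask@contoured)
  if (length(cont) < 2L)
    stop("apical exclusion needs >= 2 contoured slices")
  mask@excludedApical[max(cont)] <- TRUE
  mask
}
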