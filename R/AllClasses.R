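#' @import methods
NULL

## Central data containers. All voxel arrays are indexed [row, col, slice];
## slice 1 is the most basal slice, coordinates are 1-based and pixel-centred.

#' ImageStack: a short-axis signal-intensity volume with physical geometry
#'
#' Holds a 3-D greyscale signal-intensity (SI) array in arbitrary units,
#' indexed `[row, col, slice]` with slice 1 the most basal slice, together
#' with in-plane pixel spacing (mm), slice thickness (mm), inter-slice gap
#' (mm) and a modality tag (`"LGE"` or `"T2w"`). An optional image-quality
#' grade (0 = unanalysable to 3 = excellent) is carried as pass-through
#' metadata and never used by any computation.
#'
#' @slot voxels numeric 3-D array of signal intensity.
#' @slot pixelSpacing numeric length-2, (row, col) spacing in mm.
#' @slot sliceThickness numeric, slice thickness in mm.
#' @slot sliceGap numeric, inter-slice gap in mm (>= 0).
#' @slot modality character, `"LGE"` or `"T2w"`.
#' @slot qualityGrade integer 0-3 or NA.
#'
#' @seealso [imageStack()], [readStack()], [generatePhantom()]
#' @export
setClass("ImageStack",
  representation(
    voxels = "array",
    pixelSpacing = "numeric",
    sliceThickness = "numeric",
    sliceGap = "numeric",
    modality = "character",
    qualityGrade = "integer"
  ),
  prototype(sliceGap = 0, modality = "LGE", qualityGrade = NA_integer_)
)

setValidity("ImageStack", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L) return("voxels must be a 3-D array [row, col, slice]")
  if (dim(v)[3] < 2L) return("an ImageStack needs >= 2 slices (interslice-continuity logic)")
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    return("pixelSpacing must be two positive values (mm)")
  if (length(object@sliceThickness) != 1L || object@sliceThickness <= 0)
    return("sliceThickness must be a single positive value (mm)")
  if (length(object@sliceGap) != 1L || object@sliceGap < 0)
    return("sliceGap must be a single value >= 0 (mm)")
  if (!object@modality %in% c("LGE", "T2w"))
    return("modality must be 'LGE' or 'T2w'")
  if (length(object@qualityGrade) != 1L ||
      (!is.na(object@qualityGrade) && !object@qualityGrade %in% 0:3))
    return("qualityGrade must be a single NA or integer in 0..3")
  TRUE
})

#' ContourSet: per-slice endocardial and epicardial polygons
#'
#' A list of contoured slices; each element is `list(slice =, endo =, epi =)`
#' where `endo` and `epi` are 2-column matrices of `[row, col]` vertices in
#' 1-based pixel-centred coordinates. Polygons are implicitly closed (the
#' last vertex connects to the first).
#'
#' @slot contours list of per-slice contour entries.
#' @export
setClass("ContourSet", representation(contours = "list"))

setValidity("ContourSet", function(object) {
  for (entry in object@contours) {
    if (!all(c("slice", "endo", "epi") %in% names(entry)))
      return("each contour entry needs fields slice, endo, epi")
    for (role in c("endo", "epi")) {
      poly <- entry[[role]]
      if (!is.matrix(poly) || ncol(poly) != 2L || nrow(poly) < 3L)
        return(sprintf("%s polygon on slice %s must be a matrix with >= 3 [row, col] vertices",
                       role, entry$slice))
    }
  }
  slices <- vapply(object@contours, function(e) as.integer(e$slice), integer(1))
  if (anyDuplicated(slices)) return("duplicate slice index in ContourSet")
  TRUE
})

#' MyoMask: rasterised myocardial mask with per-slice bookkeeping
#'
#' Boolean volume aligned with an [ImageStack-class]; TRUE where the voxel
#' centre lies inside the epicardial and outside the endocardial contour.
#' Per-slice flags record which slices were contoured and which have been
#' excluded as the most apical slice. "Quantifiable" slices (contoured and
#' not excluded) are the only slices that contribute to enhancement and to
#' the %LVM denominator under the default mass convention.
#'
#' @slot mask logical 3-D array.
#' @slot contoured logical per-slice flag.
#' @slot excludedApical logical per-slice flag.
#' @export
setClass("MyoMask",
  representation(mask = "array", contoured = "logical", excludedApical = "logical"))

setValidity("MyoMask", function(object) {
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
    return("mask must be a logical 3-D array")
  ns <- dim(object@mask)[3]
  if (length(object@contoured) != ns || length(object@excludedApical) != ns)
    return("per-slice flags must have one entry per slice")
  uncont <- which(!object@contoured)
  if (length(uncont) && any(object@mask[, , uncont, drop = FALSE]))
    return("mask voxels present on a slice flagged as not contoured")
  TRUE
})

#' Roi: a fixed-area region of interest within the myocardium of one slice
#'
#' @slot slice integer slice index.
#' @slot voxels 2-column integer matrix of member `[row, col]` voxels.
#' @slot targetAreaCm2 numeric target area in cm^2 (default 2 in builders).
#' @slot kind character, `"remote"` or `"infarct-core"`.
#' @export
setClass("Roi",
  representation(slice = "integer", voxels = "matrix",
                 targetAreaCm2 = "numeric", kind = "character"))

setValidity("Roi", function(object) {
  if (ncol(object@voxels) != 2L || nrow(object@voxels) < 1L)
    return("voxels must be a non-empty 2-column [row, col] matrix")
  if (!object@kind %in% c("remote", "infarct-core"))
    return("kind must be 'remote' or 'infarct-core'")
  TRUE
})

#' PhantomSpec: parameters of the synthetic short-axis phantom
#'
#' Describes an idealised annular LV myocardium (concentric circles per
#' slice) containing a circular-sector infarct of given angular extent and
#' transmurality, an oedema (area-at-risk) wedge exceeding the infarct wedge
#' by an angular margin, an optional enclosed hypointense core (MVO on LGE,
#' IMH on T2w) occupying a fraction of the infarct area, isolated
#' false-enhancement speckles in remote territory, in-plane Gaussian
#' partial-volume blur and additive Gaussian noise.
#'
#' Signal-intensity levels are arbitrary units. `siLgeBorder` is the LGE
#' intensity of the peri-infarct oedema border zone (intermediate between
#' remote and infarct in the default, realistic configuration; set it equal
#' to `siRemote` for a fully separable noise-free phantom).
#'
#' @slot nSlices,matrixSize integer counts.
#' @slot pixelSpacing,sliceThickness,sliceGap mm.
#' @slot endoRadius,epiRadius mm.
#' @slot infarctCenterDeg,infarctExtentDeg,oedemaMarginDeg degrees.
#' @slot infarctTransmurality fraction 0-1 (from the endocardium outward).
#' @slot infarctSlices integer vector of slice indices carrying infarct.
#' @slot mvoFraction fraction (0 <= f < 1) of infarct area forming the core.
#' @slot siRemote,siInfarct,siOedema,siMvo,siBlood,siBackground,siLgeBorder SI means.
#' @slot noiseSd additive Gaussian noise SD (SI units).
#' @slot blurSigmaMm in-plane partial-volume blur scale (mm).
#' @slot speckleCount integer count of single-slice false-enhancement specks.
#' @slot seed integer RNG seed.
#' @seealso [phantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec",
  representation(
    nSlices = "integer", matrixSize = "integer",
    pixelSpacing = "numeric", sliceThickness = "numeric", sliceGap = "numeric",
    endoRadius = "numeric", epiRadius = "numeric",
    infarctCenterDeg = "numeric", infarctExtentDeg = "numeric",
    infarctTransmurality = "numeric", infarctSlices = "integer",
    oedemaMarginDeg = "numeric", mvoFraction = "numeric",
    siRemote = "numeric", siInfarct = "numeric", siOedema = "numeric",
    siMvo = "numeric", siBlood = "numeric", siBackground = "numeric",
    siLgeBorder = "numeric",
    noiseSd = "numeric", blurSigmaMm = "numeric",
    speckleCount = "integer", seed = "integer"
  ))

setValidity("PhantomSpec", function(object) {
  if (object@nSlices < 2L) return("nSlices must be >= 2")
  if (object@endoRadius <= 0 || object@epiRadius <= object@endoRadius)
    return("need 0 < endoRadius < epiRadius")
  fov_half <- (object@matrixSize - 1) / 2 * object@pixelSpacing
  if (object@epiRadius >= fov_half)
    return("epicardial radius does not fit inside the image matrix")
  if (object@infarctTransmurality < 0 || object@infarctTransmurality > 1)
    return("infarctTransmurality must be in [0, 1]")
  if (object@mvoFraction < 0 || object@mvoFraction >= 1)
    return("mvoFraction must be in [0, 1)")
  if (object@infarctExtentDeg < 0 || object@infarctExtentDeg > 360)
    return("infarctExtentDeg must be in [0, 360]")
  if (object@oedemaMarginDeg < 0) return("oedemaMarginDeg must be >= 0")
  if (length(object@infarctSlices) &&
      (min(object@infarctSlices) < 1L || max(object@infarctSlices) > object@nSlices))
    return("infarctSlices out of range")
  if (object@siInfarct <= object@siRemote)
    return("need siInfarct > siRemote (LGE hyperenhancement)")
  if (object@siOedema <= object@siRemote)
    return("need siOedema > siRemote (T2w hyperintensity)")
  if (object@siMvo >= object@siInfarct)
    return("need siMvo < siInfarct (hypointense core)")
  if (object@noiseSd < 0 || object@blurSigmaMm < 0)
    return("noiseSd and blurSigmaMm must be >= 0")
  if (object@speckleCount < 0L) return("speckleCount must be >= 0")
  TRUE
})

#' GroundTruth: exact masks and reference percentages of a phantom
#'
#' All masks are logical volumes aligned with the generated stacks. The
#' reference percentages follow the pipeline's default mass convention: the
#' most apical slice is excluded from both the numerator and the denominator.
#'
#' @slot myoMask,infarctMask,oedemaMask,mvoMask,imhMask,speckleMask logical arrays.
#' @slot trueIsPercent,trueAarPercent,trueMsi percentages.
#' @export
setClass("GroundTruth",
  representation(
    myoMask = "array", infarctMask = "array", oedemaMask = "array",
    mvoMask = "array", imhMask = "array", speckleMask = "array",
    trueIsPercent = "numeric", trueAarPercent = "numeric", trueMsi = "numeric"
  ))

setValidity("GroundTruth", function(object) {
  if (any(object@infarctMask & !object@myoMask)) return("infarct not within myocardium")
  if (any(object@oedemaMask & !object@myoMask)) return("oedema not within myocardium")
  if (any(object@infarctMask & !object@oedemaMask))
    return("infarct not within oedema (infarct must lie within the area at risk)")
  if (any(object@mvoMask & !object@infarctMask)) return("MVO not within infarct")
  TRUE
})

#' QuantResult: one quantification method's output
#'
#' @slot method character label (`"5SD"`..`"8SD"`, `"2SD"`, `"FWHM"`, `"OAT"`, `"manual"`).
#' @slot thresholds numeric per-slice SI thresholds (NA on non-quantifiable or
#'   degenerate slices; a single shared value replicated for kSD/FWHM).
#' @slot remoteStats numeric `c(mu =, sd =)` of the remote ROI (kSD) or NAs.
#' @slot coreMax numeric maximum core SI (FWHM) or NA.
#' @slot enhancementMask logical volume of enhanced voxels.
#' @slot enhancedMassG numeric enhanced mass in grams.
#' @slot percentLvm numeric IS or AAR as % of LV mass.
#' @slot correctionsApplied logical `c(fill =, noise =)`.
#' @export
setClass("QuantResult",
  representation(
    method = "character", thresholds = "numeric", remoteStats = "numeric",
    coreMax = "numeric", enhancementMask = "array", enhancedMassG = "numeric",
    percentLvm = "numeric", correctionsApplied = "logical"
  ))

setValidity("QuantResult", function(object) {
  if (!is.logical(object@enhancementMask)) return("enhancementMask must be logical")
  if (!all(c("fill", "noise") %in% names(object@correctionsApplied)))
    return("correctionsApplied must be named c(fill =, noise =)")
  if (object@percentLvm < 0 || object@percentLvm > 100)
    return("percentLvm must be within [0, 100]")
  TRUE
})

#' SalvageResult: myocardial salvage index and its inputs
#'
#' @slot aarPercent,isPercent,msi percentages; `msi = 100 * (aar - is) / aar`.
#' @export
setClass("SalvageResult",
  representation(aarPercent = "numeric", isPercent = "numeric", msi = "numeric"))

#' AgreementReport: agreement of one measurement series against a reference
#'
#' @slot n integer number of paired subjects.
#' @slot icc,iccCategory intraclass correlation (absolute agreement, single
#'   measure) and its qualitative category.
#' @slot bias,loaLow,loaHigh Bland-Altman mean difference and 1.96 SD limits.
#' @slot pairedTP two-sided paired t-test p-value.
#' @export
setClass("AgreementReport",
  representation(n = "integer", icc = "numeric", iccCategory = "character",
                 bias = "numeric", loaLow = "numeric", loaHigh = "numeric",
                 pairedTP = "numeric"))

setValidity("AgreementReport", function(object) {
  if (!is.na(object@icc) && (object@icc < -1 || object@icc > 1))
    return("icc must be in [-1, 1]")
  if (!is.na(object@bias) &&
      (object@loaLow > object@bias || object@bias > object@loaHigh))
    return("need loaLow <= bias <= loaHigh")
  TRUE
})

#' CohortConfig: configuration of a phantom-cohort comparison run
#'
#' @slot specs list of [PhantomSpec-class] objects, one per subject.
#' @slot methodsIs,methodsAar character method labels for IS (LGE) and AAR (T2w).
#' @slot measures character subset of `c("IS", "AAR")`.
#' @slot nObservers,nReplicates,manualRaters,manualReplicates integer design sizes.
#' @slot contourJitterSd radial contour-vertex jitter, pixels.
#' @slot roiJitterSd ROI seed jitter, pixels.
#' @slot manualJitterSd jitter of manual (visual) measurements, %LVM.
#' @slot fieldStrength character label carried into the ratings table.
#' @slot seed integer master seed.
#' @export
setClass("CohortConfig",
  representation(
    specs = "list", methodsIs = "character", methodsAar = "character",
    measures = "character", nObservers = "integer", nReplicates = "integer",
    manualRaters = "integer", manualReplicates = "integer",
    contourJitterSd = "numeric", roiJitterSd = "numeric",
    manualJitterSd = "numeric", fieldStrength = "character", seed = "integer"
  ))

setValidity("CohortConfig", function(object) {
  if (!length(object@specs)) return("cohort needs >= 1 subject spec")
  if (!all(vapply(object@specs, is, logical(1), "PhantomSpec")))
    return("specs must all be PhantomSpec objects")
  if (!all(object@measures %in% c("IS", "AAR")))
    return("measures must be a subset of c('IS', 'AAR')")
  if (object@nObservers < 1L || object@nReplicates < 1L)
    return("need >= 1 observer and >= 1 replicate")
  TRUE
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageStack (%s): %d x %d x %d voxels\n", object@modality, d[1], d[2], d[3]))
  cat(sprintf("  pixel spacing %.3g x %.3g mm, thickness %.3g mm, gap %.3g mm\n",
              object@pixelSpacing[1], object@pixelSpacing[2],
              object@sliceThickness, object@sliceGap))
  if (!is.na(object@qualityGrade))
    cat(sprintf("  quality grade %d\n", object@qualityGrade))
})

setMethod("show", "MyoMask", function(object) {
  q <- which(object@contoured & !object@excludedApical)
  cat(sprintf("MyoMask: %d myocardial voxels on %d contoured slices (%d quantifiable)\n",
              sum(object@mask), sum(object@contoured), length(q)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d slices of %dx%d px (%.3g mm), annulus %.3g-%.3g mm\n",
              object@nSlices, object@matrixSize, object@matrixSize,
              object@pixelSpacing, object@endoRadius, object@epiRadius))
  cat(sprintf("  infarct %.3g deg x transmurality %.3g on slices %s; MVO fraction %.3g\n",
              object@infarctExtentDeg, object@infarctTransmurality,
              paste(range(object@infarctSlices), collapse = "-"), object@mvoFraction))
  cat(sprintf("  noise SD %.3g, blur %.3g mm, %d speckles, seed %d\n",
              object@noiseSd, object@blurSigmaMm, object@speckleCount, object@seed))
})

setMethod("show", "QuantResult", function(object) {
  thr <- object@thresholds[!is.na(object@thresholds)]
  cat(sprintf("QuantResult [%s]: %.2f %%LVM (%.2f g enhanced)\n",
              object@method, object@percentLvm, object@enhancedMassG))
  if (length(thr))
    cat(sprintf("  threshold(s): %s\n",
                paste(formatC(unique(round(thr, 3))), collapse = ", ")))
  cat(sprintf("  corrections: fill=%s, noise=%s\n",
              object@correctionsApplied[["fill"]], object@correctionsApplied[["noise"]]))
})

setMethod("show", "SalvageResult", function(object) {
  cat(sprintf("SalvageResult: AAR %.2f%%, IS %.2f%%, MSI %.2f%%\n",
              object@aarPercent, object@isPercent, object@msi))
})

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("AgreementReport (n = %d)\n", object@n))
  cat(sprintf("  ICC %.3f (%s)\n", object@icc, object@iccCategory))
  cat(sprintf("  bias %+.2f (LoA %+.2f, %+.2f), paired t p = %.4g\n",
              object@bias, object@loaHigh, object@loaLow, object@pairedTP))
})
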