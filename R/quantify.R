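## Thresholding methods and correction operators: the measurement core.
## All methods use a strict enhancement test (SI > T) and operate only on
## quantifiable slices (contoured, not apically excluded).

.quantifiableMyo <- function(mask) {
  q <- quantifiableSlices(mask)
  m <- array(FALSE, dim(mask@mask))
  m[, , q] <- mask@mask[, , q, drop = FALSE]
  m
}

.percentOfLvm <- function(enh_count, mask, apicalInDenominator = FALSE) {
  sl <- if (apicalInDenominator) contouredSlices(mask) else quantifiableSlices(mask)
  denom <- sum(mask@mask[, , sl, drop = FALSE])
  if (denom == 0L) stop("zero myocardial mass: %LVM undefined")
  100 * enh_count / denom
}

.makeQuantResult <- function(method, enh, thresholds, mask, stack,
                             remoteStats = c(mu = NA_real_, sd = NA_real_),
                             coreMax = NA_real_,
                             corrections = c(fill = FALSE, noise = FALSE),
                             apicalInDenominator = FALSE) {
  new("QuantResult", method = method, thresholds = thresholds,
      remoteStats = remoteStats, coreMax = coreMax, enhancementMask = enh,
      enhancedMassG = .voxelMassG(sum(enh), stack),
      percentLvm = .percentOfLvm(sum(enh), mask, apicalInDenominator),
      correctionsApplied = corrections)
}

#' k-standard-deviation remote-ROI thresholding
#'
#' The classic kSD method: the mean and sample standard deviation (n - 1
#' denominator) of the signal intensity inside a remote-myocardium ROI define
#' one global threshold `T = mu + k * sd`, applied to all quantifiable
#' slices; a voxel is enhanced iff `SI > T`. k = 5..8 is used for infarct
#' size on LGE and k = 2 for the area at risk on T2w-STIR. A degenerate ROI
#' with zero spread is permitted (the threshold is then the ROI mean).
#' Corrections are not applied here; see [fillEnclosedCores()] and
#' [removeNoiseIslands()].
#'
#' @param stack an [ImageStack-class].
#' @param mask the matching [MyoMask-class].
#' @param remoteRoi an [Roi-class] in remote myocardium.
#' @param k positive SD multiplier.
#' @return a [QuantResult-class] labelled `"<k>SD"`.
#' @export
thresholdKSD <- function(stack, mask, remoteRoi, k) {
  stopifnot(is(stack, "ImageStack"), is(mask, "MyoMask"), is(remoteRoi, "Roi"))
  if (!is.numeric(k) || length(k) != 1L || k <= 0) stop("k must be a positive scalar")
  vals <- voxels(stack)[cbind(remoteRoi@voxels, remoteRoi@slice)]
  if (!length(vals)) stop("empty remote ROI")
  mu <- mean(vals)
  sd_ <- if (length(vals) > 1L) stats::sd(vals) else 0
  thr <- mu + k * sd_
  qmyo <- .quantifiableMyo(mask)
  enh <- qmyo & voxels(stack) > thr
  thr_vec <- rep(NA_real_, nSlices(mask))
  thr_vec[quantifiableSlices(mask)] <- thr
  label <- if (k == round(k)) sprintf("%dSD", as.integer(k)) else sprintf("%gSD", k)
  .makeQuantResult(label, enh, thr_vec, mask, stack,
                   remoteStats = c(mu = mu, sd = sd_))
}

#' Full-width-half-maximum (FWHM) thresholding
#'
#' The threshold is half the maximum signal intensity in the infarct core:
#' `T = 0.5 * SImax`, one shared value for all slices; enhanced iff
#' `SI > T`. With a core ROI, `SImax` is the ROI maximum; in automatic mode
#' (`coreRoi = NULL`) it is the global maximum over all quantifiable
#' myocardium, which is what the manual candidate-ROI search reduces to since
#' only the single brightest pixel matters -- this also makes the method
#' insensitive to ROI size.
#'
#' @inheritParams thresholdKSD
#' @param coreRoi an [Roi-class] in the infarct core, or NULL for automatic
#'   core search.
#' @return a [QuantResult-class] labelled `"FWHM"`.
#' @export
thresholdFWHM <- function(stack, mask, coreRoi = NULL) {
  stopifnot(is(stack, "ImageStack"), is(mask, "MyoMask"))
  qmyo <- .quantifiableMyo(mask)
  if (!any(qmyo)) stop("empty myocardium: FWHM threshold undefined")
  core_max <- if (is.null(coreRoi)) {
    max(voxels(stack)[qmyo])
  } else {
    stopifnot(is(coreRoi, "Roi"))
    max(voxels(stack)[cbind(coreRoi@voxels, coreRoi@slice)])
  }
  thr <- 0.5 * core_max
  enh <- qmyo & voxels(stack) > thr
  thr_vec <- rep(NA_real_, nSlices(mask))
  thr_vec[quantifiableSlices(mask)] <- thr
  .makeQuantResult("FWHM", enh, thr_vec, mask, stack, coreMax = core_max)
}

#' Per-slice Otsu automated thresholding (OAT)
#'
#' For every quantifiable slice a 256-bin histogram is built over that
#' slice's myocardial signal-intensity range and the threshold minimising the
#' within-class variance sum (equivalently maximising the between-class
#' variance) is chosen, ties broken toward the lowest threshold; enhanced iff
#' `SI > T_slice`. A threshold is computed on every slice whether or not it
#' contains infarct -- this is the method's documented overestimation
#' mechanism on infarct-free slices. A constant-intensity slice is a
#' zero-variance degenerate: it gets no enhancement and a warning.
#'
#' @inheritParams thresholdKSD
#' @param nbins histogram bin count (default 256).
#' @return a [QuantResult-class] labelled `"OAT"` with one threshold per
#'   slice.
#' @export
thresholdOtsu <- function(stack, mask, nbins = 256L) {
  stopifnot(is(stack, "ImageStack"), is(mask, "MyoMask"))
  d <- dim(mask@mask)
  enh <- array(FALSE, d)
  thr_vec <- rep(NA_real_, d[3])
  for (s in quantifiableSlices(mask)) {
    myo_s <- mask@mask[, , s]
    vals <- voxels(stack)[, , s][myo_s]
    if (length(vals) < 2L)
      stop(sprintf("slice %d has < 2 myocardial voxels: Otsu undefined", s))
    t_s <- .otsuThreshold(vals, nbins)
    if (is.na(t_s)) {
      warning(sprintf("constant signal intensity on slice %d: no enhancement designated", s))
      next
    }
    thr_vec[s] <- t_s
    sl <- myo_s & voxels(stack)[, , s] > t_s
    enh[, , s] <- sl
  }
  .makeQuantResult("OAT", enh, thr_vec, mask, stack)
}

#' Correction [a]: include enclosed hypointense cores
#'
#' Adds to the enhancement mask, slice by slice, every non-enhanced
#' myocardial 2-D component (8-connectivity) whose entire boundary is
#' enhanced -- i.e. every pixel neighbouring the component but outside it is
#' an enhanced voxel. These enclosed cores correspond to microvascular
#' obstruction on LGE and intramyocardial haemorrhage on T2w, which belong to
#' the total infarct and area at risk respectively. Components touching
#' remote myocardium, the blood pool or the epicardial edge are left alone.
#' Idempotent.
#'
#' @param result a [QuantResult-class].
#' @param mask the [MyoMask-class] used to compute it.
#' @param stack the matching [ImageStack-class].
#' @return the corrected [QuantResult-class] (flag `fill` set).
#' @export
fillEnclosedCores <- function(result, mask, stack) {
  stopifnot(is(result, "QuantResult"), is(mask, "MyoMask"))
  enh <- result@enhancementMask
  d <- dim(enh)
  offs <- .neighbourOffsets(2L)
  for (s in quantifiableSlices(mask)) {
    enh_s <- enh[, , s]
    hole_cand <- mask@mask[, , s] & !enh_s
    if (!any(hole_cand)) next
    labels <- .labelComponents(hole_cand)
    for (lab in seq_len(max(labels))) {
      comp <- which(labels == lab)
      rc <- arrayInd(comp, d[1:2])
      nb <- rc[rep(seq_len(nrow(rc)), each = nrow(offs)), , drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), times = nrow(rc)), , drop = FALSE]
      inb <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L & nb[, 2] <= d[2]
      if (!all(inb)) next  # touches the image edge: not enclosed
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1]
      outside <- setdiff(lin, comp)
      if (length(outside) && all(enh_s[outside])) {
        enh_s[comp] <- TRUE
      }
    }
    enh[, , s] <- enh_s
  }
  corr <- result@correctionsApplied
  corr[["fill"]] <- TRUE
  .makeQuantResult(result@method, enh, result@thresholds, mask, stack,
                   remoteStats = result@remoteStats, coreMax = result@coreMax,
                   corrections = corr)
}

#' Correction [b]: remove isolated enhancement without interslice continuity
#'
#' Removes 3-D connected components (26-connectivity) of enhancement that
#' span fewer than `minSliceSpan` slices, unless they intersect
#' `protectMask`. The protect mask stands in for knowledge of the
#' infarct-related artery territory (e.g. the oedema wedge or an
#' observer-supplied sector); with the default `NULL` the rule is purely the
#' interslice-continuity criterion. Idempotent.
#'
#' @inheritParams fillEnclosedCores
#' @param minSliceSpan minimum number of slices a component must span to be
#'   retained (default 2).
#' @param protectMask optional logical volume; intersecting components are
#'   always kept.
#' @return the corrected [QuantResult-class] (flag `noise` set).
#' @export
removeNoiseIslands <- function(result, mask, stack, minSliceSpan = 2L,
                               protectMask = NULL) {
  stopifnot(is(result, "QuantResult"), is(mask, "MyoMask"))
  if (minSliceSpan < 2L) stop("minSliceSpan must be >= 2")
  enh <- result@enhancementMask
  labels <- .labelComponents(enh)
  if (max(labels) > 0L) {
    idx <- which(labels > 0L)
    sl <- arrayInd(idx, dim(enh))[, 3]
    lab <- labels[idx]
    span <- vapply(split(sl, lab), function(x) length(unique(x)), integer(1))
    protected <- rep(FALSE, max(labels))
    if (!is.null(protectMask)) {
      pm <- protectMask[idx]
      protected[unique(lab[pm])] <- TRUE
    }
    drop_labs <- as.integer(names(span))[span < minSliceSpan & !protected]
    if (length(drop_labs)) enh[idx[lab %in% drop_labs]] <- FALSE
  }
  corr <- result@correctionsApplied
  corr[["noise"]] <- TRUE
  .makeQuantResult(result@method, enh, result@thresholds, mask, stack,
                   remoteStats = result@remoteStats, coreMax = result@coreMax,
                   corrections = corr)
}

#' Express an enhancement mask as percent of LV mass
#'
#' `100 x enhanced mass / LV mass` over quantifiable slices; the myocardial
#' density cancels. With `apicalInDenominator = TRUE` the excluded apical
#' slice's mass is kept in the denominator (the alternative convention);
#' enhancement is always restricted to quantifiable slices.
#'
#' @inheritParams fillEnclosedCores
#' @param apicalInDenominator keep excluded-slice mass in the denominator.
#' @return percentage (numeric scalar).
#' @export
percentLVM <- function(result, mask, stack, apicalInDenominator = FALSE) {
  stopifnot(is(result, "QuantResult"), is(mask, "MyoMask"))
  .percentOfLvm(sum(result@enhancementMask), mask, apicalInDenominator)
}

#' Manual reference as the mean of repeated analyses
#'
#' In the absence of a gold standard, the manual reference is the arithmetic
#' mean of repeated manual quantifications (conventionally six: two each by
#' three readers).
#'
#' @param replicates numeric vector of replicate %LVM values, a list of
#'   [QuantResult-class] objects, or a data frame with a `value` column (and
#'   optionally `subject`/`measure` columns, which must then be constant).
#' @return the mean %LVM.
#' @export
manualReference <- function(replicates) {
  if (is.data.frame(replicates)) {
    for (col in c("subject", "measure")) {
      if (col %in% names(replicates) && length(unique(replicates[[col]])) > 1L)
        stop(sprintf("replicates mix several values of '%s'", col))
    }
    replicates <- replicates$value
  } else if (is.list(replicates)) {
    replicates <- vapply(replicates, function(r) {
      stopifnot(is(r, "QuantResult")); r@percentLvm
    }, numeric(1))
  }
  if (!length(replicates)) stop("need >= 1 replicate")
  mean(as.numeric(replicates))
}

#' Myocardial salvage index
#'
#' `MSI = 100 * (AAR - IS) / AAR`: the proportion of the reversibly injured
#' area at risk that did not infarct. `IS > AAR` is physically inconsistent
#' but can occur across methods; it is reported as computed with a warning.
#'
#' @param aar area at risk, %LVM (> 0).
#' @param is_ infarct size, %LVM.
#' @return a [SalvageResult-class].
#' @export
salvageIndex <- function(aar, is_) {
  if (!is.numeric(aar) || aar <= 0) stop("MSI undefined: AAR must be > 0")
  if (is_ > aar) warning("IS exceeds AAR; negative MSI reported as computed")
  new("SalvageResult", aarPercent = as.numeric(aar), isPercent = as.numeric(is_),
      msi = 100 * (aar - is_) / aar)
}
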