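## Cohort orchestration: run every quantification method over a cohort of
## phantoms with simulated observers, assemble the long-format ratings table,
## and emit the accuracy/reproducibility report tables.

#' Build a cohort configuration
#'
#' Observer variability on phantoms is simulated at its true sources: the
#' per-slice endo/epi contour vertices are jittered radially and the remote
#' ROI seed is jittered in-plane, per observer and per replicate. Manual
#' (visual) quantification is simulated as the ground-truth value plus
#' measurement jitter; the manual reference is the mean of
#' `manualRaters x manualReplicates` analyses (default 3 x 2 = 6).
#'
#' @param specs list of [PhantomSpec-class] (one per subject; give each its
#'   own seed).
#' @param methodsIs,methodsAar method labels for IS (LGE) and AAR (T2w);
#'   `"MANUAL"` is always included as the reference.
#' @param measures subset of `c("IS", "AAR")`.
#' @param nObservers,nReplicates semi-automated analysis design.
#' @param manualRaters,manualReplicates manual reference design.
#' @param contourJitterSd radial vertex jitter SD, pixels.
#' @param roiJitterSd ROI seed jitter SD, pixels.
#' @param manualJitterSd manual measurement jitter SD, %LVM.
#' @param fieldStrength label carried into the ratings table.
#' @param seed master seed for the whole run.
#' @return a [CohortConfig-class].
#' @export
cohortConfig <- function(specs,
                         methodsIs = c("FWHM", "5SD", "6SD", "7SD", "8SD", "OAT"),
                         methodsAar = c("2SD", "OAT"),
                         measures = c("IS", "AAR"),
                         nObservers = 2L, nReplicates = 2L,
                         manualRaters = 3L, manualReplicates = 2L,
                         contourJitterSd = 0.4, roiJitterSd = 1.0,
                         manualJitterSd = 1.0, fieldStrength = "1.5T",
                         seed = 1L) {
  new("CohortConfig", specs = specs, methodsIs = methodsIs,
      methodsAar = methodsAar, measures = measures,
      nObservers = as.integer(nObservers), nReplicates = as.integer(nReplicates),
      manualRaters = as.integer(manualRaters),
      manualReplicates = as.integer(manualReplicates),
      contourJitterSd = contourJitterSd, roiJitterSd = roiJitterSd,
      manualJitterSd = manualJitterSd, fieldStrength = fieldStrength,
      seed = as.integer(seed))
}

## Radial jitter of a polygon's vertices about its centroid.
.jitterPoly <- function(poly, sd) {
  if (sd <= 0) return(poly)
  ctr <- colMeans(poly)
  dirs <- sweep(poly, 2, ctr)
  nrm <- sqrt(rowSums(dirs^2))
  nrm[nrm == 0] <- 1
  poly + dirs / nrm * stats::rnorm(nrow(poly), 0, sd)
}

.jitterContours <- function(contours, sd) {
  if (sd <= 0) return(contours)
  entries <- lapply(contours@contours, function(e)
    list(slice = e$slice, endo = .jitterPoly(e$endo, sd),
         epi = .jitterPoly(e$epi, sd)))
  new("ContourSet", contours = entries)
}

## Nearest myocardial voxel to a (possibly non-myocardial) point on a slice.
.snapToMyo <- function(mask, slice, seed) {
  d <- dim(mask@mask)
  rc <- arrayInd(which(mask@mask[, , slice]), d[1:2])
  if (!nrow(rc)) stop("no myocardium on slice ", slice)
  i <- which.min((rc[, 1] - seed[1])^2 + (rc[, 2] - seed[2])^2)
  rc[i, ]
}

## Remote-ROI placement emulating an observer: the ROI is anchored at the
## requested in-plane position, but among the quantifiable slices the one
## whose candidate ROI is least contaminated by enhancement (smallest ROI
## maximum SI) is chosen -- a reader never draws the remote ROI over a
## visible bright speck.
.placeRemoteRoi <- function(stack, mask, seedPx, preferSlice, roiAreaCm2 = 2) {
  cand <- quantifiableSlices(mask)
  cand <- cand[order(abs(cand - preferSlice))]
  best <- NULL
  best_max <- Inf
  for (s in cand) {
    roi <- tryCatch({
      seed_rc <- .snapToMyo(mask, s, seedPx)
      buildRoi(mask, stack, s, seed_rc, roiAreaCm2, kind = "remote")
    }, error = function(e) NULL)
    if (is.null(roi)) next
    mx <- max(voxels(stack)[cbind(roi@voxels, roi@slice)])
    if (mx < best_max) {
      best <- roi
      best_max <- mx
    }
  }
  if (is.null(best)) stop("no slice can host a remote ROI of the requested area")
  best
}

## One corrected measurement of one method on one stack/mask.
.runMethod <- function(method, stack, mask, remoteSeedPx, remoteSlice,
                       roiAreaCm2 = 2) {
  res <- if (grepl("^[0-9.]+SD$", method)) {
    k <- as.numeric(sub("SD$", "", method))
    roi <- .placeRemoteRoi(stack, mask, remoteSeedPx, remoteSlice, roiAreaCm2)
    thresholdKSD(stack, mask, roi, k)
  } else if (method == "FWHM") {
    thresholdFWHM(stack, mask)
  } else if (method == "OAT") {
    suppressWarnings(thresholdOtsu(stack, mask))
  } else stop("unknown method: ", method)
  res <- fillEnclosedCores(res, mask, stack)
  removeNoiseIslands(res, mask, stack)
}

#' Run the full method comparison over a phantom cohort
#'
#' For every subject x measure x method x observer x replicate, a corrected
#' %LVM measurement is produced (manual corrections [enclosed-core fill,
#' interslice-continuity noise removal] are always applied). Returns the
#' long-format ratings table, the per-measure report tables (means, ICC and
#' Bland-Altman versus the manual reference, interobserver and intraobserver
#' blocks, via [reproduceSupplementary()]) and a provenance table of
#' thresholds and masses. Deterministic given the config seed; any subject
#' failing quantification aborts with a subject-labelled error.
#'
#' @param config a [CohortConfig-class].
#' @return list with elements `ratings`, `reports` (named by measure),
#'   `truth` (per-subject true percentages) and `provenance`.
#' @export
runCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  rows <- list()
  prov <- list()
  truth_rows <- list()
  .withSeed(config@seed, {
    for (i in seq_along(config@specs)) {
      subj <- sprintf("S%02d", i)
      res <- tryCatch(
        .runSubject(config, config@specs[[i]], subj),
        error = function(e) stop("subject ", subj, ": ", conditionMessage(e),
                                 call. = FALSE))
      rows[[i]] <- res$rows
      prov[[i]] <- res$prov
      truth_rows[[i]] <- res$truth
    }
  })
  ratings <- .asRatingsTable(do.call(rbind, rows), source = "cohort ratings")
  reports <- lapply(stats::setNames(nm = config@measures), function(ms)
    reproduceSupplementary(ratings[ratings$measure == ms, ]))
  list(ratings = ratings, reports = reports,
       truth = do.call(rbind, truth_rows), provenance = do.call(rbind, prov))
}

.runSubject <- function(config, spec, subj) {
  ph <- generatePhantom(spec)
  rows <- list()
  prov <- list()
  mid <- function(mask) {
    q <- quantifiableSlices(mask)
    q[ceiling(length(q) / 2)]
  }
  c0 <- (spec@matrixSize + 1) / 2
  remote_angle <- (spec@infarctCenterDeg + 180) * pi / 180
  rm_mid <- (spec@endoRadius + spec@epiRadius) / 2 / spec@pixelSpacing
  base_seed <- c(c0 + rm_mid * sin(remote_angle), c0 + rm_mid * cos(remote_angle))

  for (ms in config@measures) {
    stack <- if (ms == "IS") ph$lge else ph$t2w
    methods <- if (ms == "IS") config@methodsIs else config@methodsAar
    true_val <- if (ms == "IS") ph$truth@trueIsPercent else ph$truth@trueAarPercent
    for (o in seq_len(config@nObservers)) {
      for (r in seq_len(config@nReplicates)) {
        cset <- .jitterContours(ph$contours, config@contourJitterSd)
        mask <- excludeApicalSlice(rasterizeContours(cset, stack))
        sl <- mid(mask)
        seed_px <- base_seed + stats::rnorm(2, 0, config@roiJitterSd)
        for (m in methods) {
          qr <- .runMethod(m, stack, mask, seed_px, sl)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = subj, field_strength = config@fieldStrength, measure = ms,
            method = m, rater = sprintf("Obs%d", o), replicate = r,
            value = qr@percentLvm, stringsAsFactors = FALSE)
          thr <- qr@thresholds[!is.na(qr@thresholds)]
          prov[[length(prov) + 1L]] <- data.frame(
            subject = subj, measure = ms, method = m,
            rater = sprintf("Obs%d", o), replicate = r,
            threshold = if (length(thr)) thr[1] else NA_real_,
            enhanced_mass_g = qr@enhancedMassG, percent_lvm = qr@percentLvm,
            stringsAsFactors = FALSE)
        }
      }
    }
    for (mr in seq_len(config@manualRaters)) {
      for (r in seq_len(config@manualReplicates)) {
        val <- min(100, max(0, true_val + stats::rnorm(1, 0, config@manualJitterSd)))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj, field_strength = config@fieldStrength, measure = ms,
          method = "MANUAL", rater = sprintf("Man%d", mr), replicate = r,
          value = val, stringsAsFactors = FALSE)
      }
    }
  }
  list(rows = do.call(rbind, rows), prov = do.call(rbind, prov),
       truth = data.frame(subject = subj,
                          true_is = ph$truth@trueIsPercent,
                          true_aar = ph$truth@trueAarPercent,
                          true_msi = ph$truth@trueMsi,
                          stringsAsFactors = FALSE))
}

#' Recompute summary report tables from a raw ratings table
#'
#' From a long-format ratings table (one row per subject x measure x method
#' x rater x replicate) this recomputes, per field strength, measure and
#' method: cohort mean and SD, ICC and Bland-Altman bias (with 1.96 SD
#' limits) and paired-t p against the reference method, and the
#' interobserver (first vs second rater, first replicate) and intraobserver
#' (first rater, first vs second replicate) ICC and Bland-Altman blocks --
#' the layout of the standard accuracy/reproducibility result tables. The
#' reference value per subject is the mean of all reference-method rows
#' (the mean-of-repeated-analyses policy).
#'
#' A `mapping` can be supplied to ingest externally named tables; it is
#' applied by [readRatings()] semantics when `ratings` is a file path.
#'
#' @param ratings a ratings data frame, or a CSV path.
#' @param reference reference method label (default `"MANUAL"`).
#' @param iccType passed to [iccAgreement()].
#' @param mapping optional column mapping when `ratings` is a path.
#' @return a data frame with one row per field strength x measure x method.
#' @export
reproduceSupplementary <- function(ratings, reference = "MANUAL",
                                   iccType = "agreement", mapping = NULL) {
  if (is.character(ratings)) ratings <- readRatings(ratings, mapping)
  ratings <- .asRatingsTable(ratings)
  out <- list()
  for (fs in unique(ratings$field_strength)) {
    for (ms in unique(ratings$measure[ratings$field_strength == fs])) {
      g <- ratings[ratings$field_strength == fs & ratings$measure == ms, ]
      subjects <- sort(unique(g$subject))
      has_ref <- reference %in% g$method
      ref_val <- if (has_ref) {
        vapply(subjects, function(s)
          mean(g$value[g$subject == s & g$method == reference]), numeric(1))
      } else NULL
      pick <- function(m, rt, rp) {
        v <- vapply(subjects, function(s) {
          sel <- g$subject == s & g$method == m & g$rater == rt & g$replicate == rp
          if (sum(sel) != 1L) NA_real_ else g$value[sel]
        }, numeric(1))
        if (anyNA(v)) NULL else v
      }
      for (m in unique(g$method)) {
        raters <- sort(unique(g$rater[g$method == m]))
        reps <- sort(unique(g$replicate[g$method == m]))
        primary <- pick(m, raters[1], reps[1])
        if (is.null(primary))
          stop(sprintf("incomplete ratings for method %s (%s, %s)", m, fs, ms))
        row <- data.frame(
          field_strength = fs, measure = ms, method = m,
          n = length(subjects), mean = mean(primary), sd = stats::sd(primary),
          icc_v_ref = NA_real_, bias_v_ref = NA_real_,
          loa_low = NA_real_, loa_high = NA_real_, p_v_ref = NA_real_,
          interobs_icc = NA_real_, interobs_bias = NA_real_,
          interobs_loa_low = NA_real_, interobs_loa_high = NA_real_,
          intraobs_icc = NA_real_, intraobs_bias = NA_real_,
          intraobs_loa_low = NA_real_, intraobs_loa_high = NA_real_,
          stringsAsFactors = FALSE)
        if (has_ref && m != reference) {
          rep_ <- agreementReport(primary, ref_val, iccType = iccType)
          row$icc_v_ref <- rep_@icc
          row$bias_v_ref <- rep_@bias
          row$loa_low <- rep_@loaLow
          row$loa_high <- rep_@loaHigh
          row$p_v_ref <- rep_@pairedTP
        }
        if (length(raters) >= 2L) {
          a <- pick(m, raters[1], reps[1]); b <- pick(m, raters[2], reps[1])
          if (!is.null(a) && !is.null(b)) {
            ba <- blandAltman(a, b)
            row$interobs_icc <- tryCatch(iccAgreement(cbind(a, b), type = iccType),
                                         error = function(e) NA_real_)
            row$interobs_bias <- ba[["bias"]]
            row$interobs_loa_low <- ba[["loa_low"]]
            row$interobs_loa_high <- ba[["loa_high"]]
          }
        }
        if (length(reps) >= 2L) {
          a <- pick(m, raters[1], reps[1]); b <- pick(m, raters[1], reps[2])
          if (!is.null(a) && !is.null(b)) {
            ba <- blandAltman(a, b)
            row$intraobs_icc <- tryCatch(iccAgreement(cbind(a, b), type = iccType),
                                         error = function(e) NA_real_)
            row$intraobs_bias <- ba[["bias"]]
            row$intraobs_loa_low <- ba[["loa_low"]]
            row$intraobs_loa_high <- ba[["loa_high"]]
          }
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  do.call(rbind, out)
}
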