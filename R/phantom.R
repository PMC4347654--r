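#' Build a phantom specification
#'
#' Defaults describe a realistic acute-infarct short-axis study: a 128 x 128
#' matrix at 1.5 mm spacing, 9 slices of 8 mm with a 2 mm gap, an annular
#' myocardium of 22-32 mm radius, a 90-degree subendocardial infarct of 75%
#' transmurality on the 5 central slices inside a transmural oedema wedge 15
#' degrees wider on each side, a 15% enclosed hypointense core, an
#' intermediate-intensity LGE border zone, 1 mm partial-volume blur, additive
#' Gaussian noise and three single-slice false-enhancement speckles in remote
#' territory.
#'
#' @param nSlices,matrixSize,pixelSpacing,sliceThickness,sliceGap geometry.
#' @param endoRadius,epiRadius annulus radii, mm.
#' @param infarctCenterDeg,infarctExtentDeg infarct wedge centre and extent.
#' @param infarctTransmurality fraction of wall depth, from the endocardium.
#' @param infarctSlices slice indices carrying infarct (default: central
#'   slices, sparing the two most basal and the two most apical).
#' @param oedemaMarginDeg extra angular margin of the oedema wedge, per side.
#' @param mvoFraction fraction of infarct area forming the enclosed core.
#' @param siRemote,siInfarct,siOedema,siMvo,siBlood,siBackground,siLgeBorder
#'   signal-intensity means (arbitrary units). `siLgeBorder` is the LGE
#'   intensity of the oedematous border zone; set it to `siRemote` for a
#'   fully separable phantom.
#' @param noiseSd,blurSigmaMm noise and partial-volume scales.
#' @param speckleCount number of isolated false-enhancement specks.
#' @param seed RNG seed.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(nSlices = 9L, matrixSize = 128L, pixelSpacing = 1.5,
                        sliceThickness = 8, sliceGap = 2,
                        endoRadius = 22, epiRadius = 32,
                        infarctCenterDeg = 90, infarctExtentDeg = 90,
                        infarctTransmurality = 0.75,
                        infarctSlices = NULL,
                        oedemaMarginDeg = 15, mvoFraction = 0.15,
                        siRemote = 100, siInfarct = 400, siOedema = 200,
                        siMvo = 50, siBlood = 300, siBackground = 20,
                        siLgeBorder = 170,
                        noiseSd = 10, blurSigmaMm = 1, speckleCount = 3L,
                        seed = 1L) {
  if (is.null(infarctSlices)) {
    lo <- min(3L, nSlices - 1L)
    hi <- max(lo, nSlices - 2L)
    infarctSlices <- lo:hi
  }
  new("PhantomSpec",
      nSlices = as.integer(nSlices), matrixSize = as.integer(matrixSize),
      pixelSpacing = pixelSpacing, sliceThickness = sliceThickness,
      sliceGap = sliceGap, endoRadius = endoRadius, epiRadius = epiRadius,
      infarctCenterDeg = infarctCenterDeg, infarctExtentDeg = infarctExtentDeg,
      infarctTransmurality = infarctTransmurality,
      infarctSlices = as.integer(infarctSlices),
      oedemaMarginDeg = oedemaMarginDeg, mvoFraction = mvoFraction,
      siRemote = siRemote, siInfarct = siInfarct, siOedema = siOedema,
      siMvo = siMvo, siBlood = siBlood, siBackground = siBackground,
      siLgeBorder = siLgeBorder, noiseSd = noiseSd, blurSigmaMm = blurSigmaMm,
      speckleCount = as.integer(speckleCount), seed = as.integer(seed))
}

## Circle contour polygon in pixel coordinates (row, col), 180 vertices.
.circlePoly <- function(radius_mm, centre_px, spacing) {
  th <- seq(0, 2 * pi, length.out = 181L)[-181L]
  rp <- radius_mm / spacing
  cbind(row = centre_px + rp * sin(th), col = centre_px + rp * cos(th))
}

## Signed angular distance (degrees) from a reference direction, in (-180, 180].
.angDist <- function(theta, ref) {
  ((theta - ref + 180) %% 360) - 180
}

#' Generate a paired LGE / T2w-STIR phantom with ground truth
#'
#' Builds the noiseless per-region signal-intensity maps (regions have
#' exactly the specified means before blur and noise), applies in-plane
#' Gaussian blur and additive Gaussian noise, and returns both modality
#' stacks, the endo/epi contours that trace the true circles, and a
#' [GroundTruth-class] with exact masks and reference percentages. Identical
#' seeds reproduce bit-identical output. Speckles are single-slice
#' enhancement components placed outside the oedema wedge at mutually
#' distinct angles, so they are disconnected (in 3-D, 26-connectivity) from
#' the infarct and from each other.
#'
#' @param spec a [PhantomSpec-class].
#' @return a list with elements `lge`, `t2w` ([ImageStack-class]),
#'   `contours` ([ContourSet-class]) and `truth` ([GroundTruth-class]).
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  m <- spec@matrixSize
  ns <- spec@nSlices
  sp <- spec@pixelSpacing
  c0 <- (m + 1) / 2

  endo_poly <- .circlePoly(spec@endoRadius, c0, sp)
  epi_poly <- .circlePoly(spec@epiRadius, c0, sp)

  rows <- matrix(seq_len(m), m, m)
  cols <- t(rows)
  r_mm <- sqrt(((rows - c0) * sp)^2 + ((cols - c0) * sp)^2)
  theta <- (atan2(rows - c0, cols - c0) * 180 / pi) %% 360
  ## signed angular distance; wedge membership is half-open (-e/2, e/2] so
  ## that lattice-aligned wedge edges are counted once, not twice
  sdist <- .angDist(theta, spec@infarctCenterDeg)
  in_wedge <- function(extent) sdist > -extent / 2 & sdist <= extent / 2
  adist <- abs(sdist)

  myo2 <- .rasterizeSlicePolys(endo_poly, epi_poly, m, m)
  blood2 <- matrix(.pointsInPolygon(as.vector(cols), as.vector(rows),
                                    endo_poly[, 2], endo_poly[, 1]), m, m)

  r_trans <- spec@endoRadius +
    spec@infarctTransmurality * (spec@epiRadius - spec@endoRadius)
  infarct2 <- myo2 & in_wedge(spec@infarctExtentDeg) & r_mm <= r_trans
  oedema2 <- myo2 & in_wedge(spec@infarctExtentDeg + 2 * spec@oedemaMarginDeg)
  if (spec@infarctTransmurality == 0 || spec@infarctExtentDeg == 0)
    infarct2 <- infarct2 & FALSE

  mvo2 <- matrix(FALSE, m, m)
  if (spec@mvoFraction > 0 && any(infarct2)) {
    s <- sqrt(spec@mvoFraction)
    rm_ <- (spec@endoRadius + r_trans) / 2
    H <- (r_trans - spec@endoRadius) / 2
    mvo2 <- infarct2 & abs(r_mm - rm_) <= H * s &
      in_wedge(spec@infarctExtentDeg * s)
  }

  inf_slices <- spec@infarctSlices

  myoV <- array(rep(myo2, ns), c(m, m, ns))
  infarctV <- array(FALSE, c(m, m, ns))
  oedemaV <- array(FALSE, c(m, m, ns))
  mvoV <- array(FALSE, c(m, m, ns))
  for (s in inf_slices) {
    infarctV[, , s] <- infarct2
    oedemaV[, , s] <- oedema2
    mvoV[, , s] <- mvo2
  }

  ## base noiseless 2-D SI maps
  lge_plain <- matrix(spec@siBackground, m, m)
  lge_plain[blood2] <- spec@siBlood
  lge_plain[myo2] <- spec@siRemote
  t2w_plain <- lge_plain
  lge_inf <- lge_plain
  lge_inf[oedema2] <- spec@siLgeBorder
  lge_inf[infarct2] <- spec@siInfarct
  lge_inf[mvo2] <- spec@siMvo
  t2w_inf <- t2w_plain
  t2w_inf[oedema2] <- spec@siOedema
  t2w_inf[mvo2] <- spec@siMvo

  lgeV <- array(0, c(m, m, ns))
  t2wV <- array(0, c(m, m, ns))
  for (s in seq_len(ns)) {
    if (s %in% inf_slices) {
      lgeV[, , s] <- lge_inf
      t2wV[, , s] <- t2w_inf
    } else {
      lgeV[, , s] <- lge_plain
      t2wV[, , s] <- t2w_plain
    }
  }

  speckleV <- array(FALSE, c(m, m, ns))
  out <- .withSeed(spec@seed, {
    if (spec@speckleCount > 0L) {
      buffer <- 15
      ang_cand <- seq(0, 340, by = 20)
      ok <- abs(.angDist(ang_cand, spec@infarctCenterDeg)) >
        spec@infarctExtentDeg / 2 + spec@oedemaMarginDeg + buffer
      ang_cand <- ang_cand[ok]
      if (length(ang_cand) < spec@speckleCount)
        stop("not enough remote territory for the requested speckle count")
      angs <- sample(ang_cand, spec@speckleCount)
      slcs <- sample(seq_len(ns), spec@speckleCount, replace = TRUE)
      rm_mid <- (spec@endoRadius + spec@epiRadius) / 2
      for (i in seq_len(spec@speckleCount)) {
        a <- angs[i] * pi / 180
        pr <- c0 + rm_mid / sp * sin(a)
        pc <- c0 + rm_mid / sp * cos(a)
        speck <- myo2 & sqrt((rows - pr)^2 + (cols - pc)^2) <= 1.2
        speckleV[, , slcs[i]] <- speckleV[, , slcs[i]] | speck
        lgeV[, , slcs[i]][speck] <- spec@siInfarct
        t2wV[, , slcs[i]][speck] <- spec@siOedema
      }
    }
    if (spec@blurSigmaMm > 0) {
      sig_px <- spec@blurSigmaMm / sp
      for (s in seq_len(ns)) {
        lgeV[, , s] <- .blurSlice(lgeV[, , s], sig_px)
        t2wV[, , s] <- .blurSlice(t2wV[, , s], sig_px)
      }
    }
    if (spec@noiseSd > 0) {
      lgeV <- lgeV + array(stats::rnorm(length(lgeV), sd = spec@noiseSd), dim(lgeV))
      t2wV <- t2wV + array(stats::rnorm(length(t2wV), sd = spec@noiseSd), dim(t2wV))
    }
    list(lge = lgeV, t2w = t2wV, speckle = speckleV)
  })

  contours <- contourSet(lapply(seq_len(ns), function(s)
    list(slice = s, endo = endo_poly, epi = epi_poly)))

  ## reference percentages under the default convention: the most apical
  ## slice is excluded from both numerator and denominator
  q <- seq_len(ns - 1L)
  myo_n <- sum(myoV[, , q])
  true_is <- 100 * sum(infarctV[, , q]) / myo_n
  true_aar <- 100 * sum(oedemaV[, , q]) / myo_n
  true_msi <- if (true_aar > 0) 100 * (true_aar - true_is) / true_aar else NA_real_

  truth <- new("GroundTruth",
    myoMask = myoV, infarctMask = infarctV, oedemaMask = oedemaV,
    mvoMask = mvoV, imhMask = mvoV, speckleMask = out$speckle,
    trueIsPercent = true_is, trueAarPercent = true_aar, trueMsi = true_msi)

  list(
    lge = imageStack(out$lge, sp, spec@sliceThickness, spec@sliceGap, "LGE"),
    t2w = imageStack(out$t2w, sp, spec@sliceThickness, spec@sliceGap, "T2w"),
    contours = contours,
    truth = truth
  )
}

#' Sample a synthetic observer-measurement table
#'
#' Emits a long-format ratings table in which each measurement is a latent
#' per-subject true value plus a per-method bias plus independent Gaussian
#' noise. Latent values are drawn from a normal distribution whose default
#' mean and SD match a typical manually quantified acute infarct-size
#' distribution; values are truncated to [0, 100] %LVM.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param biasPerMethod named numeric vector: method label -> bias (%LVM).
#' @param noiseSd measurement noise SD (%LVM).
#' @param seed RNG seed.
#' @param measure `"IS"` or `"AAR"`.
#' @param fieldStrength label carried into the table.
#' @param trueMean,trueSd latent true-value distribution (%LVM).
#' @param raters,replicates rater labels and replicate indices to emit (each
#'   rater x replicate gets independent noise).
#' @return a long-format data frame with columns `subject`, `field_strength`,
#'   `measure`, `method`, `rater`, `replicate`, `value`.
#' @export
sampleObserverTable <- function(nSubjects, biasPerMethod, noiseSd, seed = 1L,
                                measure = c("IS", "AAR"), fieldStrength = "1.5T",
                                trueMean = 16.5, trueSd = 10.3,
                                raters = "R1", replicates = 1L) {
  measure <- match.arg(measure)
  if (nSubjects < 2L) stop("need >= 2 subjects")
  if (is.null(names(biasPerMethod)) || any(!nzchar(names(biasPerMethod))))
    stop("biasPerMethod must be a named vector (method label -> bias)")
  .withSeed(seed, {
    truth <- pmin(100, pmax(0, stats::rnorm(nSubjects, trueMean, trueSd)))
    grid <- expand.grid(subject = sprintf("S%02d", seq_len(nSubjects)),
                        method = names(biasPerMethod),
                        rater = raters, replicate = as.integer(replicates),
                        stringsAsFactors = FALSE)
    val <- truth[match(grid$subject, sprintf("S%02d", seq_len(nSubjects)))] +
      biasPerMethod[grid$method] +
      stats::rnorm(nrow(grid), 0, noiseSd)
    data.frame(subject = grid$subject, field_strength = fieldStrength,
               measure = measure, method = grid$method, rater = grid$rater,
               replicate = grid$replicate,
               value = unname(pmin(100, pmax(0, val))),
               stringsAsFactors = FALSE)
  })
}
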