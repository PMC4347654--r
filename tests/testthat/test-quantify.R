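# hand-built two-slice scene used by the threshold/correction unit tests
flatScene <- function(si = 100, nr = 12, nc = 12) {
  v <- array(si, c(nr, nc, 2))
  myo <- array(TRUE, c(nr, nc, 2))
  stack <- imageStack(v, 1, 10, 0)
  mask <- new("MyoMask", mask = myo, contoured = c(TRUE, TRUE),
              excludedApical = c(FALSE, FALSE))
  list(stack = stack, mask = mask)
}

roiOf <- function(rows, cols, slice = 1L, kind = "remote") {
  new("Roi", slice = as.integer(slice),
      voxels = cbind(row = as.integer(rows), col = as.integer(cols)),
      targetAreaCm2 = 2, kind = kind)
}

test_that("kSD threshold is exactly mu + k * sample SD", {
  sc <- flatScene()
  # ROI values with mu = 100, sample SD = 10
  vals <- c(90, 90, 110, 110, 100)
  stopifnot(mean(vals) == 100, sd(vals) == 10)
  sc$stack@voxels[1, 1:5, 1] <- vals
  roi <- roiOf(rep(1, 5), 1:5)
  r5 <- thresholdKSD(sc$stack, sc$mask, roi, 5)
  expect_equal(r5@thresholds[1], 150)
  expect_equal(unname(r5@remoteStats), c(100, 10))
  # k = 8, mu = 0, sample sd = 1
  v2 <- c(-1, -1, 0, 1, 1)
  stopifnot(mean(v2) == 0, sd(v2) == 1)
  sc$stack@voxels[1, 1:5, 1] <- v2
  r8 <- thresholdKSD(sc$stack, sc$mask, roiOf(rep(1, 5), 1:5), 8)
  expect_equal(r8@thresholds[1], 8)
  # degenerate zero-spread ROI still defines a threshold
  sc2 <- flatScene()
  r0 <- thresholdKSD(sc2$stack, sc2$mask, roiOf(1, 1), 5)
  expect_equal(r0@thresholds[1], 100)
  expect_error(thresholdKSD(sc2$stack, sc2$mask, roiOf(1, 1), -2), "positive")
})

test_that("FWHM threshold is half the core maximum; uniform myocardium is the degenerate", {
  sc <- flatScene()
  sc$stack@voxels[3, 3, 1] <- 200
  r <- thresholdFWHM(sc$stack, sc$mask)  # auto core search
  expect_equal(r@coreMax, 200)
  expect_equal(r@thresholds[1], 100)
  # explicit core ROI
  r2 <- thresholdFWHM(sc$stack, sc$mask, roiOf(3, 3, kind = "infarct-core"))
  expect_equal(r2@thresholds[1], 100)
  # uniform SI 50: T = 25 and the whole myocardium is "enhanced"
  sc3 <- flatScene(si = 50)
  r3 <- thresholdFWHM(sc3$stack, sc3$mask)
  expect_equal(r3@thresholds[1], 25)
  expect_equal(r3@percentLvm, 100)
})

test_that("per-slice Otsu separates a two-level slice and flags constant slices", {
  sc <- flatScene(si = 5)
  sc$stack@voxels[1, 1:6, 1] <- c(1, 1, 1, 9, 9, 9)
  sc$mask@mask[] <- FALSE
  sc$mask@mask[1, 1:6, 1] <- TRUE
  sc$mask@mask[1, 1:4, 2] <- TRUE   # constant slice [5,5,5,5]
  expect_warning(r <- thresholdOtsu(sc$stack, sc$mask), "constant")
  expect_gt(r@thresholds[1], 1); expect_lt(r@thresholds[1], 9)
  expect_equal(sum(r@enhancementMask[, , 1]), 3)
  expect_true(is.na(r@thresholds[2]))
  expect_equal(sum(r@enhancementMask[, , 2]), 0)
})

test_that("Otsu equals the exhaustive within-class-variance oracle on small slices", {
  set.seed(99)
  for (i in 1:50) {
    vals <- round(runif(sample(3:12, 1), 0, 100), 1)
    if (length(unique(vals)) == 1L) next
    expect_identical(cmrquant:::.otsuThreshold(vals), otsuOracle(vals))
  }
})

test_that("Otsu lands between two well-separated intensity modes", {
  set.seed(7)
  vals <- c(rnorm(60, 100, 15), rnorm(40, 400, 15))
  t_ <- cmrquant:::.otsuThreshold(vals)
  expect_identical(t_, otsuOracle(vals))
  expect_gt(t_, 100); expect_lt(t_, 400)
})

test_that("enclosed-core filling adds fully surrounded holes and nothing else", {
  sc <- flatScene()
  enh <- array(FALSE, dim(sc$mask@mask))
  enh[3:9, 3:9, 1] <- TRUE
  enh[5:6, 5:6, 1] <- FALSE          # 4-voxel fully enclosed hole
  enh[3:9, 3, 2] <- TRUE             # wall with a notch open to remote myo
  enh[5, 3, 2] <- FALSE
  res <- new("QuantResult", method = "5SD",
             thresholds = c(150, 150), remoteStats = c(mu = 100, sd = 10),
             coreMax = NA_real_, enhancementMask = enh,
             enhancedMassG = 0, percentLvm = 0,
             correctionsApplied = c(fill = FALSE, noise = FALSE))
  out <- fillEnclosedCores(res, sc$mask, sc$stack)
  expect_equal(sum(out@enhancementMask[, , 1]) - sum(enh[, , 1]), 4)
  # the notch touches non-enhanced myocardium around it: not filled
  expect_equal(out@enhancementMask[5, 3, 2], FALSE)
  expect_true(out@correctionsApplied[["fill"]])
  # idempotent
  expect_identical(fillEnclosedCores(out, sc$mask, sc$stack)@enhancementMask,
                   out@enhancementMask)
})

test_that("interslice-continuity correction removes single-slice islands only", {
  sc <- flatScene(nr = 16, nc = 16)
  enh <- array(FALSE, dim(sc$mask@mask))
  enh[3:6, 3:6, 1] <- TRUE; enh[3:6, 3:6, 2] <- TRUE  # 2-slice component
  enh[12:13, 12, 1] <- TRUE                            # 1-slice speck
  res <- new("QuantResult", method = "FWHM", thresholds = c(1, 1),
             remoteStats = c(mu = NA_real_, sd = NA_real_), coreMax = 2,
             enhancementMask = enh, enhancedMassG = 0, percentLvm = 0,
             correctionsApplied = c(fill = FALSE, noise = FALSE))
  out <- removeNoiseIslands(res, sc$mask, sc$stack)
  expect_equal(sum(out@enhancementMask), 32)
  expect_false(any(out@enhancementMask[12:13, 12, 1]))
  # protect mask keeps the speck
  pm <- array(FALSE, dim(enh)); pm[12, 12, 1] <- TRUE
  out2 <- removeNoiseIslands(res, sc$mask, sc$stack, protectMask = pm)
  expect_equal(sum(out2@enhancementMask), 34)
  # idempotent
  expect_identical(removeNoiseIslands(out, sc$mask, sc$stack)@enhancementMask,
                   out@enhancementMask)
})

test_that("corrections recover exact truth on separable phantoms with MVO and speckles", {
  spec <- fineSeparableSpec(mvoFraction = 0.2, speckleCount = 3L, seed = 21L)
  ph <- generatePhantom(spec)
  mask <- excludeApicalSlice(rasterizeContours(ph$contours, ph$lge))
  roi <- buildRoi(mask, ph$lge, 3, remoteSeed(spec), 2)
  raw <- thresholdKSD(ph$lge, mask, roi, 5)
  # before corrections: the large enclosed core is missing (speckles add back
  # much less than it removes), so raw IS underestimates truth
  expect_lt(raw@percentLvm, ph$truth@trueIsPercent)
  fixed <- removeNoiseIslands(fillEnclosedCores(raw, mask, ph$lge), mask, ph$lge)
  expect_lt(abs(fixed@percentLvm - ph$truth@trueIsPercent), 0.5)
  # corrections commute on this input
  other <- fillEnclosedCores(removeNoiseIslands(raw, mask, ph$lge), mask, ph$lge)
  expect_identical(fixed@enhancementMask, other@enhancementMask)
})

test_that("every intermediate threshold segments the separable phantom exactly", {
  spec <- fineSeparableSpec(speckleCount = 0L, seed = 13L)
  ph <- generatePhantom(spec)
  mask <- excludeApicalSlice(rasterizeContours(ph$contours, ph$lge))
  qmyo <- cmrquant:::.quantifiableMyo(mask)
  q <- quantifiableSlices(mask)
  ns <- spec@nSlices
  truth_q <- ph$truth@infarctMask
  truth_q[, , setdiff(seq_len(ns), q)] <- FALSE
  for (t_ in c(150, 250, 399)) {
    enh <- qmyo & voxels(ph$lge) > t_
    res <- new("QuantResult", method = "manual", thresholds = rep(t_, ns),
               remoteStats = c(mu = NA_real_, sd = NA_real_), coreMax = NA_real_,
               enhancementMask = enh, enhancedMassG = 0, percentLvm = 0,
               correctionsApplied = c(fill = FALSE, noise = FALSE))
    out <- fillEnclosedCores(res, mask, ph$lge)
    expect_identical(out@enhancementMask, truth_q)
  }
})

test_that("percent of LV mass, manual reference and salvage index follow their formulas", {
  sc <- flatScene()
  enh <- array(FALSE, dim(sc$mask@mask))
  enh[1:6, 1:12, 1] <- TRUE  # 72 of 288 voxels
  res <- new("QuantResult", method = "manual",
             thresholds = c(NA_real_, NA_real_),
             remoteStats = c(mu = NA_real_, sd = NA_real_), coreMax = NA_real_,
             enhancementMask = enh, enhancedMassG = 0, percentLvm = 0,
             correctionsApplied = c(fill = FALSE, noise = FALSE))
  expect_equal(percentLVM(res, sc$mask, sc$stack), 25)
  res@enhancementMask[] <- FALSE
  expect_equal(percentLVM(res, sc$mask, sc$stack), 0)

  expect_equal(manualReference(c(10, 12, 14, 10, 12, 14)), 12)
  expect_equal(manualReference(17.3), 17.3)
  expect_error(manualReference(data.frame(subject = c("a", "b"), value = c(1, 2))),
               "mix")

  expect_equal(msi(salvageIndex(40, 10)), 75)
  expect_equal(msi(salvageIndex(30, 30)), 0)
  expect_equal(msi(salvageIndex(30, 0)), 100)
  expect_warning(s <- salvageIndex(10, 12), "exceeds")
  expect_lt(msi(s), 0)
  expect_error(salvageIndex(0, 5), "AAR")
})

test_that("kSD infarct size is non-increasing in k for a shared remote ROI", {
  for (i in 1:5) {
    spec <- tinySpec(seed = 30L + i)
    ph <- generatePhantom(spec)
    mask <- excludeApicalSlice(rasterizeContours(ph$contours, ph$lge))
    roi <- cmrquant:::.placeRemoteRoi(ph$lge, mask, remoteSeed(spec), 3)
    vals <- vapply(5:8, function(k)
      thresholdKSD(ph$lge, mask, roi, k)@percentLvm, numeric(1))
    expect_true(all(diff(vals) <= 0))
  }
})
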