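make_circle <- function(r_px, c0, n = 180L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(c0 + r_px * sin(th), c0 + r_px * cos(th))
}

test_that("concentric circles rasterise to the analytic annulus area", {
  # radii 20/30 mm at 1 mm spacing
  stack <- imageStack(array(0, c(80, 80, 2)), 1, 8)
  cs <- contourSet(list(
    list(slice = 1, endo = make_circle(20, 40.5), epi = make_circle(30, 40.5)),
    list(slice = 2, endo = make_circle(20, 40.5), epi = make_circle(30, 40.5))))
  mask <- rasterizeContours(cs, stack)
  area <- sum(maskArray(mask)[, , 1])  # 1 mm^2 voxels
  expect_lt(abs(area - pi * (30^2 - 20^2)) / (pi * 500), 0.01)
})

test_that("degenerate and inverted contours are handled", {
  stack <- imageStack(array(0, c(40, 40, 2)), 1, 8)
  same <- make_circle(10, 20.5)
  expect_warning(
    mask <- rasterizeContours(contourSet(list(
      list(slice = 1, endo = same, epi = same),
      list(slice = 2, endo = make_circle(5, 20.5), epi = make_circle(10, 20.5)))),
      stack),
    "coincide")
  expect_equal(sum(maskArray(mask)[, , 1]), 0)
  expect_error(
    rasterizeContours(contourSet(list(
      list(slice = 1, endo = make_circle(12, 20.5), epi = make_circle(10, 20.5)),
      list(slice = 2, endo = make_circle(5, 20.5), epi = make_circle(10, 20.5)))),
      stack),
    "not inside")
})

test_that("phantom contours rasterise to the ground-truth myocardial mask", {
  ph <- generatePhantom(tinySpec(seed = 2L))
  mask <- rasterizeContours(ph$contours, ph$lge)
  expect_identical(maskArray(mask), ph$truth@myoMask)
})

test_that("rasterisation is rotation-consistent", {
  ph <- generatePhantom(tinySpec(seed = 4L, infarctCenterDeg = 37))
  n <- dim(voxels(ph$lge))[1]
  rot_entries <- lapply(ph$contours@contours, function(e) {
    rot <- function(p) cbind(p[, 2], n + 1 - p[, 1])  # 90-degree rotation
    list(slice = e$slice, endo = rot(e$endo), epi = rot(e$epi))
  })
  m1 <- rasterizeContours(ph$contours, ph$lge)
  m2 <- rasterizeContours(contourSet(rot_entries), ph$lge)
  expect_equal(sum(maskArray(m1)), sum(maskArray(m2)))
})

test_that("LV mass follows voxel count x geometry x density and is additive", {
  mk <- function(dims, nvox) {
    m <- array(FALSE, dims)
    m[seq_len(nvox)] <- TRUE
    new("MyoMask", mask = m, contoured = rep(TRUE, dims[3]),
        excludedApical = rep(FALSE, dims[3]))
  }
  stack <- imageStack(array(0, c(40, 40, 2)), 1, 10, 0)
  mask <- mk(c(40, 40, 2), 1000)
  expect_equal(lvMass(mask, stack), 10.5)  # 10 mL x 1.05 g/mL
  # doubling the gap from 0 to thickness doubles the mass
  stack2 <- imageStack(array(0, c(40, 40, 2)), 1, 10, 10)
  expect_equal(lvMass(mask, stack2), 21)
  # additive over disjoint slices
  m1 <- array(FALSE, c(40, 40, 2)); m1[, , 1] <- TRUE
  m2 <- array(FALSE, c(40, 40, 2)); m2[, , 2] <- TRUE
  mm <- function(a) new("MyoMask", mask = a, contoured = c(TRUE, TRUE),
                        excludedApical = c(FALSE, FALSE))
  expect_equal(lvMass(mm(m1), stack) + lvMass(mm(m2), stack),
               lvMass(mm(m1 | m2), stack))
  expect_error(lvMass(mk(c(40, 40, 2), 0), stack), "empty")
})

test_that("phantom annulus mass is within 1% of the closed-form volume", {
  spec <- tinySpec(matrixSize = 128L, pixelSpacing = 1.5)
  ph <- generatePhantom(spec)
  mask <- rasterizeContours(ph$contours, ph$lge)
  vol_ml <- pi * (spec@epiRadius^2 - spec@endoRadius^2) *
    (spec@sliceThickness + spec@sliceGap) * spec@nSlices / 1000
  expect_lt(abs(lvMass(mask, ph$lge, slices = "all") - vol_ml * 1.05) /
              (vol_ml * 1.05), 0.01)
})

test_that("ROI voxel count matches the target area and the seed must be myocardial", {
  spec <- tinySpec(matrixSize = 128L, pixelSpacing = 1.5)
  ph <- generatePhantom(spec)
  mask <- rasterizeContours(ph$contours, ph$lge)
  seed <- remoteSeed(spec)
  roi <- buildRoi(mask, ph$lge, 3, seed, 2, "remote")
  expect_equal(nrow(roi@voxels), 89)  # 200 mm^2 / 2.25 mm^2, rounded
  expect_true(all(maskArray(mask)[cbind(roi@voxels, 3L)]))
  expect_error(buildRoi(mask, ph$lge, 3, c(64.5, 64.5), 2), "not myocardial")
  expect_error(buildRoi(mask, ph$lge, 3, seed, 50), "below")
})

test_that("sub-half-pixel seed perturbations cannot change the ROI", {
  spec <- tinySpec(matrixSize = 128L, pixelSpacing = 1.5)
  ph <- generatePhantom(spec)
  mask <- rasterizeContours(ph$contours, ph$lge)
  seed <- round(remoteSeed(spec))
  ref <- buildRoi(mask, ph$lge, 3, seed, 2)
  for (dr in c(-0.49, 0, 0.49)) {
    for (dc in c(-0.49, 0, 0.49)) {
      roi <- buildRoi(mask, ph$lge, 3, seed + c(dr, dc), 2)
      expect_identical(roi@voxels, ref@voxels)
    }
  }
})

test_that("apical exclusion flags the most apical slice, once", {
  ph <- generatePhantom(tinySpec(seed = 5L))
  mask <- rasterizeContours(ph$contours, ph$lge)
  ex <- excludeApicalSlice(mask)
  expect_equal(which(ex@excludedApical), 6)
  expect_length(quantifiableSlices(ex), 5)
  expect_identical(excludeApicalSlice(ex), ex)  # idempotent
  one_arr <- mask@mask
  one_arr[, , 2:6] <- FALSE
  one <- new("MyoMask", mask = one_arr,
             contoured = c(TRUE, rep(FALSE, 5)), excludedApical = rep(FALSE, 6))
  expect_error(excludeApicalSlice(one), ">= 2 contoured")
})

test_that("uniform infarct coverage makes %LVM invariant to apical exclusion", {
  # infarct on every slice: excluding the apical slice removes the same
  # proportion from numerator and denominator
  spec <- separableSpec(infarctSlices = 1:6, speckleCount = 0L)
  ph <- generatePhantom(spec)
  mask <- rasterizeContours(ph$contours, ph$lge)
  res_all <- thresholdFWHM(ph$lge, mask)
  res_exc <- thresholdFWHM(ph$lge, excludeApicalSlice(mask))
  expect_equal(res_all@percentLvm, res_exc@percentLvm)
})
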