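# Small, fast phantom used throughout the suite (coarse grid, 6 slices).
tinySpec <- function(seed = 1L, ...) {
  args <- list(matrixSize = 64L, pixelSpacing = 3, nSlices = 6L,
               endoRadius = 22, epiRadius = 32, sliceThickness = 8,
               sliceGap = 2, infarctSlices = 2:5, seed = as.integer(seed))
  args[names(list(...))] <- list(...)
  do.call(phantomSpec, args)
}

# Fully separable phantom: no noise, no blur, border zone at remote SI.
separableSpec <- function(seed = 1L, ...) {
  tinySpec(seed = seed, noiseSd = 0, blurSigmaMm = 0, siLgeBorder = 100, ...)
}

# Separable phantom on the fine default grid (needed when the enclosed core
# must be strictly enclosed after rasterisation: the coarse test grid leaves
# sub-pixel margins).
fineSeparableSpec <- function(seed = 1L, ...) {
  args <- list(noiseSd = 0, blurSigmaMm = 0, siLgeBorder = 100,
               seed = as.integer(seed))
  args[names(list(...))] <- list(...)
  do.call(phantomSpec, args)
}

# Remote-side seed point (antipodal to the infarct wedge), pixel coords.
remoteSeed <- function(spec) {
  c0 <- (spec@matrixSize + 1) / 2
  a <- (spec@infarctCenterDeg + 180) * pi / 180
  r <- (spec@endoRadius + spec@epiRadius) / 2 / spec@pixelSpacing
  c(c0 + r * sin(a), c0 + r * cos(a))
}

# Run one corrected method measurement on a phantom (mirrors the pipeline).
quantifyPhantom <- function(ph, method, spec) {
  stack <- if (method %in% c("2SD", "OAT-AAR")) ph$t2w else ph$lge
  if (method == "OAT-AAR") method <- "OAT"
  mask <- excludeApicalSlice(rasterizeContours(ph$contours, stack))
  mid <- quantifiableSlices(mask)
  mid <- mid[ceiling(length(mid) / 2)]
  suppressWarnings(
    cmrquant:::.runMethod(method, stack, mask, remoteSeed(spec), mid))
}

# Independent Otsu oracle: per-candidate loop over the 256-bin interior
# edges, minimising the within-class SSE directly; first strict minimum kept
# (lowest threshold on ties).
otsuOracle <- function(vals, nbins = 256L) {
  rng <- range(vals)
  if (rng[1] == rng[2]) return(NA_real_)
  edges <- seq(rng[1], rng[2], length.out = nbins + 1)
  cand <- edges[2:nbins]
  best_t <- NA_real_
  best_sse <- Inf
  for (t in cand) {
    lo <- vals[vals <= t]
    hi <- vals[vals > t]
    if (!length(lo) || !length(hi)) next
    sse <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (sse < best_sse) {
      best_sse <- sse
      best_t <- t
    }
  }
  best_t
}

# Longhand two-way ANOVA ICC oracle via aov() mean squares.
iccOracleAov <- function(m, type = "agreement") {
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- nrow(m); k <- ncol(m)
  if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

# Exhaustive sign-flip enumeration oracle for the signed-rank comparison of
# squared differences (Pratt zeros: ranked with the rest, dropped from W).
wilcoxEnumOracle <- function(d1, d2) {
  z <- d1^2 - d2^2
  rk <- rank(abs(z))
  nz <- z != 0
  m <- sum(nz)
  rks <- rk[nz]
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  ws <- as.vector(signs %*% rks)
  w_obs <- sum(rks[z[nz] > 0])
  p_le <- sum(ws <= w_obs) / 2^m
  p_ge <- sum(ws >= w_obs) / 2^m
  min(1, 2 * min(p_le, p_ge))
}
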