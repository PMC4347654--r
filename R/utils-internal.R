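## Internal numerical utilities: polygon rasterisation support, connected
## components with pinned connectivity conventions, separable Gaussian blur,
## and the per-slice Otsu threshold search.

## Even-odd (crossing number) point-in-polygon, vectorised over points.
## px/py are point coordinates, vx/vy polygon vertices (implicitly closed).
## Affine-invariant under axis scaling, so it runs in pixel units.
.pointsInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    if (yi != yj) {
      cross <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
    }
    j <- i
  }
  inside
}

## Does a closed polygon self-intersect (any non-adjacent edge pair)?
## O(n^2) segment intersection; used only to warn on pathological contours.
.polygonSelfIntersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4L) return(FALSE)
  a1 <- poly
  a2 <- poly[c(2:n, 1L), , drop = FALSE]
  ## all non-adjacent edge pairs (i, j), j >= i + 2, excluding the (1, n) wrap
  idx <- which(outer(seq_len(n), seq_len(n), function(i, j)
    j >= i + 2L & !(i == 1L & j == n)), arr.ind = TRUE)
  if (!nrow(idx)) return(FALSE)
  i <- idx[, 1]; j <- idx[, 2]
  cross <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  p1x <- a1[i, 1]; p1y <- a1[i, 2]; p2x <- a2[i, 1]; p2y <- a2[i, 2]
  p3x <- a1[j, 1]; p3y <- a1[j, 2]; p4x <- a2[j, 1]; p4y <- a2[j, 2]
  d1 <- cross(p3x, p3y, p4x, p4y, p1x, p1y)
  d2 <- cross(p3x, p3y, p4x, p4y, p2x, p2y)
  d3 <- cross(p1x, p1y, p2x, p2y, p3x, p3y)
  d4 <- cross(p1x, p1y, p2x, p2y, p4x, p4y)
  any(((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

## Connected-component labelling by breadth-first flood fill.
## 2-D uses 8-connectivity, 3-D uses 26-connectivity (pinned conventions).
.neighbourOffsets <- function(ndim) {
  if (ndim == 2L) {
    g <- expand.grid(dr = -1:1, dc = -1:1)
    as.matrix(g[!(g$dr == 0 & g$dc == 0), ])
  } else {
    g <- expand.grid(dr = -1:1, dc = -1:1, ds = -1:1)
    as.matrix(g[!(g$dr == 0 & g$dc == 0 & g$ds == 0), ])
  }
}

## mask: logical matrix or 3-D array. Returns integer array of labels
## (0 = background), labelled in first-encounter order (column-major).
.labelComponents <- function(mask) {
  dm <- dim(mask)
  ndim <- length(dm)
  offs <- .neighbourOffsets(ndim)
  labels <- array(0L, dm)
  todo <- which(mask)
  if (!length(todo)) return(labels)
  coords <- arrayInd(todo, dm)
  # linear index lookup for membership tests
  in_mask <- mask
  next_label <- 0L
  visited <- array(FALSE, dm)
  for (seed in todo) {
    if (visited[seed]) next
    next_label <- next_label + 1L
    frontier <- arrayInd(seed, dm)
    visited[seed] <- TRUE
    labels[seed] <- next_label
    while (nrow(frontier)) {
      k <- nrow(frontier)
      # expand every frontier voxel by every offset
      cand <- frontier[rep(seq_len(k), each = nrow(offs)), , drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), times = k), , drop = FALSE]
      ok <- cand[, 1] >= 1L & cand[, 1] <= dm[1] & cand[, 2] >= 1L & cand[, 2] <= dm[2]
      if (ndim == 3L) ok <- ok & cand[, 3] >= 1L & cand[, 3] <= dm[3]
      cand <- cand[ok, , drop = FALSE]
      if (!nrow(cand)) break
      lin <- if (ndim == 2L) cand[, 1] + (cand[, 2] - 1L) * dm[1]
             else cand[, 1] + (cand[, 2] - 1L) * dm[1] + (cand[, 3] - 1L) * dm[1] * dm[2]
      keep <- in_mask[lin] & !visited[lin]
      lin <- unique(lin[keep])
      if (!length(lin)) break
      visited[lin] <- TRUE
      labels[lin] <- next_label
      frontier <- arrayInd(lin, dm)
    }
  }
  labels
}

## Separable in-plane Gaussian blur of one slice (matrix), sigma in pixels.
## Edges are handled by replicate padding so flat regions stay flat.
.gaussKernel1d <- function(sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  k / sum(k)
}

.blurSlice <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  k <- .gaussKernel1d(sigma_px)
  r <- (length(k) - 1L) %/% 2L
  pad_conv <- function(x) {
    # x: matrix; convolve down each column with replicate padding
    top <- x[rep(1L, r), , drop = FALSE]
    bot <- x[rep(nrow(x), r), , drop = FALSE]
    xp <- rbind(top, x, bot)
    out <- stats::filter(xp, k, sides = 2)
    matrix(out[(r + 1L):(r + nrow(x)), ], nrow = nrow(x))
  }
  t(pad_conv(t(pad_conv(m))))
}

## Otsu threshold over a vector of myocardial SI values.
##
## Candidates are the 255 interior edges of a 256-bin histogram spanning the
## value range. The within-class sum of squared errors is evaluated once per
## distinct induced partition (directly, from the raw values, not from binned
## approximations) and the lowest candidate edge of the optimal partition is
## returned -- ties therefore break toward the lowest threshold.
## Returns NA for a degenerate (constant) input.
.otsuThreshold <- function(values, nbins = 256L) {
  rng <- range(values)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) return(NA_real_)
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  cand <- edges[2:nbins]
  xs <- sort(values)
  n <- length(xs)
  ## number of values <= each candidate ("low" class; enhancement is SI > T)
  n1 <- findInterval(cand, xs)
  ok <- n1 >= 1L & n1 <= n - 1L
  if (!any(ok)) return(NA_real_)
  cand <- cand[ok]
  n1 <- n1[ok]
  splits <- unique(n1)
  sse <- vapply(splits, function(m) {
    lo <- xs[seq_len(m)]
    hi <- xs[(m + 1L):n]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, numeric(1))
  best_split <- splits[which.min(sse)]
  min(cand[n1 == best_split])
}

## Run code with a fixed seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
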