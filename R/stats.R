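## Accuracy and reproducibility statistics: two-way intraclass correlation,
## Bland-Altman limits of agreement, paired t, signed-rank comparison of
## squared differences, Pearson correlation.

#' Single-measure two-way intraclass correlation
#'
#' Two-way ANOVA decomposition of a complete subjects x raters matrix
#' (rows = subjects as random effects, columns = raters/methods as fixed
#' effects: the mixed-effects ICC(3,1) family). The default is the
#' absolute-agreement coefficient
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`,
#' which charges systematic rater offsets against agreement; the
#' `"consistency"` variant `(MSR - MSE) / (MSR + (k-1) MSE)` ignores them.
#'
#' @param ratings numeric n x k matrix, n subjects in rows, k raters in
#'   columns, no missing cells.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return the coefficient (scalar).
#' @export
iccAgreement <- function(ratings, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  x <- as.matrix(ratings)
  if (anyNA(x)) stop("missing cells: ICC requires a complete matrix (no imputation)")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 raters")
  gm <- mean(x)
  if (all(x == x[1])) stop("zero total variance: ICC undefined")
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((x - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

#' Qualitative ICC category
#'
#' Conventional bins: excellent (ICC >= 0.75), good (0.6-0.74), fair
#' (0.4-0.59), poor (< 0.40).
#'
#' @param icc coefficient in `[-1, 1]`.
#' @return `"excellent"`, `"good"`, `"fair"` or `"poor"`.
#' @export
iccCategory <- function(icc) {
  stopifnot(is.numeric(icc), icc >= -1, icc <= 1)
  if (icc >= 0.75) "excellent"
  else if (icc >= 0.6) "good"
  else if (icc >= 0.4) "fair"
  else "poor"
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are `a - b`; bias is their mean and the limits are
#' `bias +/- multiplier x SD` (sample SD, multiplier 1.96 by convention).
#'
#' @param a,b paired measurement vectors (n >= 2).
#' @param multiplier limit multiplier (default 1.96).
#' @return named vector `c(bias =, loa_low =, loa_high =)`.
#' @export
blandAltman <- function(a, b, multiplier = 1.96) {
  if (length(a) != length(b)) stop("a and b must be paired")
  if (length(a) < 2L) stop("need n >= 2 pairs")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  c(bias = bias, loa_low = bias - multiplier * s, loa_high = bias + multiplier * s)
}

#' Paired t-test p-value
#'
#' Two-sided p from `t = mean(d) / (SD(d)/sqrt(n))`, df = n - 1, with
#' `d = a - b`. All-zero differences are an error (the statistic is 0/0);
#' constant non-zero differences are the t -> infinity limit and return
#' p = 0 with a warning.
#'
#' @param a,b paired measurement vectors (n >= 2).
#' @return two-sided p-value.
#' @export
pairedT <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired")
  if (length(a) < 2L) stop("need n >= 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) stop("zero difference variance: paired t undefined")
    warning("constant non-zero differences: t -> infinity limit, p = 0")
    return(0)
  }
  stats::t.test(a, b, paired = TRUE)$p.value
}

#' Wilcoxon signed-rank comparison of squared differences
#'
#' Compares the reproducibility of two methods: for each subject,
#' `z = d1^2 - d2^2` where `d1`/`d2` are that subject's inter- or
#' intra-observer differences under method 1 and 2, and a two-sided Wilcoxon
#' signed-rank test is run on z. Zeros are handled by the Pratt convention
#' (ranked with the rest, then dropped from the statistic); tied magnitudes
#' get average ranks. The null distribution is exact (sign-flip
#' distribution, computed by convolution) for up to 25 non-zero subjects and
#' a normal approximation with tie correction above that.
#'
#' @param diffsMethod1,diffsMethod2 paired per-subject difference vectors.
#' @return two-sided p-value.
#' @export
wilcoxonSquaredDiffs <- function(diffsMethod1, diffsMethod2) {
  if (length(diffsMethod1) != length(diffsMethod2))
    stop("difference vectors must be paired per subject")
  z <- diffsMethod1^2 - diffsMethod2^2
  if (all(z == 0)) stop("all squared differences tied: test undefined")
  rk <- rank(abs(z))           # Pratt: zeros participate in ranking
  nz <- z != 0
  w_obs <- sum(rk[nz & z > 0])
  m <- sum(nz)
  if (m <= 25L) {
    ## exact sign-flip distribution over doubled (hence integer) ranks
    r2 <- as.integer(round(2 * rk[nz]))
    total <- sum(r2)
    cnt <- numeric(total + 1L)
    cnt[1L] <- 1
    for (r in r2) {
      shifted <- c(numeric(r), cnt[seq_len(total + 1L - r)])
      cnt <- cnt + shifted
    }
    w2 <- as.integer(round(2 * w_obs))
    p_le <- sum(cnt[seq_len(w2 + 1L)]) / 2^m
    p_ge <- sum(cnt[(w2 + 1L):(total + 1L)]) / 2^m
    min(1, 2 * min(p_le, p_ge))
  } else {
    n_all <- length(z)
    n0 <- n_all - m
    e_w <- (n_all * (n_all + 1) / 2 - n0 * (n0 + 1) / 2) / 4
    tie_tab <- table(rk[nz])
    tie_corr <- sum(tie_tab^3 - tie_tab) / 48
    v_w <- (n_all * (n_all + 1) * (2 * n_all + 1) -
            n0 * (n0 + 1) * (2 * n0 + 1)) / 24 - tie_corr
    zstat <- (w_obs - e_w) / sqrt(v_w)
    min(1, 2 * stats::pnorm(-abs(zstat)))
  }
}

#' Pearson correlation with two-sided p
#'
#' Standard product-moment correlation via [stats::cor.test()]; constant
#' input is an error.
#'
#' @param a,b paired vectors, n >= 3.
#' @return list with elements `r` and `p`.
#' @export
pearsonCor <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired")
  if (length(a) < 3L) stop("need n >= 3 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Agreement of one measurement series against a reference
#'
#' Convenience bundle: absolute-agreement ICC with its category,
#' Bland-Altman bias and 1.96 SD limits, and the paired t p-value (NA when
#' degenerate, e.g. identical series).
#'
#' @param x measurement vector.
#' @param ref paired reference vector.
#' @param iccType passed to [iccAgreement()].
#' @return an [AgreementReport-class].
#' @export
agreementReport <- function(x, ref, iccType = "agreement") {
  ba <- blandAltman(x, ref)
  icc <- iccAgreement(cbind(x, ref), type = iccType)
  p <- tryCatch(suppressWarnings(pairedT(x, ref)), error = function(e) NA_real_)
  new("AgreementReport", n = length(x), icc = icc,
      iccCategory = iccCategory(max(-1, min(1, icc))),
      bias = ba[["bias"]], loaLow = ba[["loa_low"]], loaHigh = ba[["loa_high"]],
      pairedTP = p)
}
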