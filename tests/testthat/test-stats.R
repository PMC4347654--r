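test_that("ICC matches the longhand ANOVA oracle and its trivial cases", {
  # identical raters, varying subjects: perfect agreement
  x <- cbind(c(1, 5, 9, 13), c(1, 5, 9, 13))
  expect_equal(iccAgreement(x), 1)
  # worked 4x2 example against the aov() oracle
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 4, 2, byrow = TRUE)
  expect_equal(iccAgreement(m), iccOracleAov(m), tolerance = 1e-12)
  expect_equal(iccAgreement(m, "consistency"), iccOracleAov(m, "consistency"),
               tolerance = 1e-12)
  expect_error(iccAgreement(cbind(c(1, NA), c(2, 3))), "missing cells")
  expect_error(iccAgreement(cbind(c(2, 2), c(2, 2))), "zero total variance")
})

test_that("a per-rater offset lowers absolute agreement but not consistency", {
  set.seed(5)
  for (i in 1:20) {
    # real subject effects, no systematic rater offsets
    m <- matrix(rnorm(8, 20, 6), 8, 3) + matrix(rnorm(8 * 3, 0, 2), 8, 3)
    m <- sweep(m, 2, colMeans(m)) + 20
    m_off <- m
    m_off[, 2] <- m_off[, 2] + 5
    expect_lt(iccAgreement(m_off), iccAgreement(m))
    expect_equal(iccAgreement(m_off, "consistency"),
                 iccAgreement(m, "consistency"), tolerance = 1e-10)
    # common constant shift changes nothing
    expect_equal(iccAgreement(m + 7), iccAgreement(m), tolerance = 1e-10)
  }
})

test_that("ICC categories use the conventional bin edges", {
  expect_equal(iccCategory(0.75), "excellent")
  expect_equal(iccCategory(0.74), "good")
  expect_equal(iccCategory(0.6), "good")
  expect_equal(iccCategory(0.59), "fair")
  expect_equal(iccCategory(0.4), "fair")
  expect_equal(iccCategory(0.39), "poor")
  expect_equal(iccCategory(-0.2), "poor")
})

test_that("Bland-Altman follows the formula and is antisymmetric", {
  a <- c(10, 12, 15, 18)
  expect_equal(unname(blandAltman(a, a)), c(0, 0, 0))
  expect_equal(unname(blandAltman(a + 5, a)), c(5, 5, 5))
  set.seed(8)
  for (i in 1:25) {
    x <- rnorm(10, 20, 5); y <- rnorm(10, 18, 5)
    ba <- blandAltman(x, y)
    d <- x - y
    expect_equal(unname(ba),
                 c(mean(d), mean(d) - 1.96 * sd(d), mean(d) + 1.96 * sd(d)))
    rev_ <- blandAltman(y, x)
    expect_identical(ba[["bias"]], -rev_[["bias"]])
    expect_identical(ba[["loa_low"]], -rev_[["loa_high"]])
    expect_identical(ba[["loa_high"]], -rev_[["loa_low"]])
  }
  expect_error(blandAltman(1, 2), "n >= 2")
})

test_that("paired t handles its degenerate limits and matches the t CDF", {
  expect_error(pairedT(c(1, 2, 3), c(1, 2, 3)), "zero difference variance")
  expect_warning(p <- pairedT(c(5, 6, 7), c(1, 2, 3)), "infinity")
  expect_equal(p, 0)
  # symmetric equal-magnitude differences: t = 0, p = 1
  expect_equal(pairedT(c(12, 8, 12, 8), c(10, 10, 10, 10)), 1)
  # seeded sample against the textbook t transform
  set.seed(31)
  a <- rnorm(10, 21, 4); b <- rnorm(10, 19, 4)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(pairedT(a, b), 2 * pt(-abs(tstat), df = 9), tolerance = 1e-12)
})

test_that("the squared-difference Wilcoxon test equals sign-flip enumeration", {
  # n = 6 toy pairs
  d1 <- c(3, 2, 4, 1, 5, 2); d2 <- c(1, 1, 2, 0, 2, 1)
  expect_identical(wilcoxonSquaredDiffs(d1, d2), wilcoxEnumOracle(d1, d2))
  # random tables for all n <= 10, with ties and zeros
  set.seed(17)
  for (n in 3:10) {
    for (rep_ in 1:5) {
      z1 <- sample(-3:3, n, replace = TRUE)
      z2 <- sample(-3:3, n, replace = TRUE)
      if (all(z1^2 == z2^2)) next
      expect_identical(wilcoxonSquaredDiffs(z1, z2), wilcoxEnumOracle(z1, z2))
    }
  }
  expect_error(wilcoxonSquaredDiffs(c(1, 2, 3), c(-1, 2, 3)), "tied")
})

test_that("a uniformly more reproducible method gives a symmetric, small p", {
  d1 <- c(5, 6, 4, 7, 5, 6, 5)   # method 1: large differences
  d2 <- c(1, 2, 1, 1, 2, 1, 1)   # method 2: uniformly smaller
  p12 <- wilcoxonSquaredDiffs(d1, d2)
  expect_lt(p12, 0.05)
  expect_identical(p12, wilcoxonSquaredDiffs(d2, d1))  # two-sided symmetry
})

test_that("large-sample Wilcoxon path approximates the exact distribution", {
  set.seed(23)
  d1 <- rnorm(30, 0, 3); d2 <- rnorm(30, 0, 1)
  p_norm <- wilcoxonSquaredDiffs(d1, d2)  # n = 30 -> normal approximation
  expect_true(p_norm >= 0 && p_norm <= 1)
  # same data truncated to 20 subjects runs the exact path; both should
  # agree on the qualitative conclusion for this clear-cut case
  p_exact <- wilcoxonSquaredDiffs(d1[1:20], d2[1:20])
  expect_lt(p_norm, 0.05)
  expect_lt(p_exact, 0.05)
})

test_that("Pearson correlation hits its exact endpoints and the formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearsonCor(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonCor(x, -x)$r, -1)
  set.seed(41)
  a <- rnorm(10); b <- rnorm(10)
  r_long <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearsonCor(a, b)$r, r_long, tolerance = 1e-12)
  expect_error(pearsonCor(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("a 5-point method bias is detected in almost every simulated cohort", {
  reject <- logical(500)
  for (i in seq_len(500)) {
    tab <- sampleObserverTable(10, c(A = 0, B = 5), noiseSd = 1, seed = i)
    a <- tab$value[tab$method == "A"]
    b <- tab$value[tab$method == "B"]
    reject[i] <- pairedT(a, b) < 0.01
  }
  expect_gte(mean(reject), 0.95)
})

test_that("agreementReport bundles ICC, Bland-Altman and the paired t", {
  set.seed(3)
  ref <- rnorm(12, 20, 6)
  x <- ref + rnorm(12, 1, 1.5)
  rep_ <- agreementReport(x, ref)
  expect_s4_class(rep_, "AgreementReport")
  expect_equal(rep_@icc, iccAgreement(cbind(x, ref)))
  ba <- blandAltman(x, ref)
  expect_equal(rep_@bias, ba[["bias"]])
  expect_equal(rep_@iccCategory, iccCategory(rep_@icc))
})
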