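test_that("exact Wilcoxon p-values match hand-enumerated cases", {
  ## complete separation of 5 vs 5: 2 / choose(10, 5) = 2/252
  expect_equal(pValue(wilcoxonRankSumExact(1:5, 6:10)), 2 / 252)
  ## interleaved 2 vs 2: doubled tail 2 * (2/6)
  expect_equal(pValue(wilcoxonRankSumExact(c(1, 3), c(2, 4))), 2 / 3,
               tolerance = 1e-12)
  ## identical groups: p = 1
  expect_equal(pValue(wilcoxonRankSumExact(c(1, 2, 3), c(1, 2, 3))), 1)
  expect_error(wilcoxonRankSumExact(numeric(0), 1:3), "non-empty")
  r <- wilcoxonRankSumExact(1:5, 6:10)
  expect_equal(r@rankSum, sum(1:5))
  expect_equal(r@method, "exact")
})

test_that("exact p matches a bit-mask permutation oracle, with and without ties", {
  withr::local_seed(51)
  for (rep in 1:40) {
    nA <- sample(1:5, 1); nB <- sample(1:5, 1)
    vals <- if (rep %% 2) round(runif(nA + nB, 0, 4)) else runif(nA + nB)
    a <- vals[seq_len(nA)]; b <- vals[nA + seq_len(nB)]
    expect_equal(pValue(wilcoxonRankSumExact(a, b)), wilcoxonOracle(a, b),
                 info = sprintf("rep %d", rep))
  }
})

test_that("p is symmetric in the groups and invariant under monotone transforms", {
  withr::local_seed(52)
  for (rep in 1:10) {
    a <- runif(4); b <- runif(5)
    p1 <- pValue(wilcoxonRankSumExact(a, b))
    expect_equal(pValue(wilcoxonRankSumExact(b, a)), p1)
    expect_equal(pValue(wilcoxonRankSumExact(exp(3 * a), exp(3 * b))), p1)
  }
})

test_that("large samples use the tie-corrected normal approximation", {
  withr::local_seed(53)
  a <- round(rnorm(15, 1), 1); b <- round(rnorm(15), 1)
  r <- wilcoxonRankSumExact(a, b)
  expect_equal(r@method, "normal-approx")
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = FALSE))
  expect_equal(pValue(r), ref$p.value, tolerance = 1e-9)
})

test_that("the deviation-based two-sided option stays a valid p-value", {
  withr::local_seed(54)
  for (rep in 1:10) {
    a <- runif(4); b <- runif(4)
    p <- pValue(wilcoxonRankSumExact(a, b, twoSided = "deviation"))
    expect_gt(p, 0); expect_lte(p, 1)
  }
  ## symmetric null: deviation and doubled-tail agree on full separation
  expect_equal(pValue(wilcoxonRankSumExact(1:4, 5:8,
                                           twoSided = "deviation")),
               pValue(wilcoxonRankSumExact(1:4, 5:8)))
})

test_that("summary ANOVA reproduces the textbook computation on raw data", {
  withr::local_seed(55)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    raw <- lapply(seq_len(k), function(i) rnorm(sample(3:8, 1), i))
    res <- anovaOnewayFromSummary(vapply(raw, mean, numeric(1)),
                                  vapply(raw, sd, numeric(1)),
                                  lengths(raw))
    df <- data.frame(y = unlist(raw),
                     g = factor(rep(seq_len(k), lengths(raw))))
    ref <- summary(stats::aov(y ~ g, df))[[1]]
    expect_equal(res$F, ref[["F value"]][1], tolerance = 1e-9)
    expect_equal(res$p, ref[["Pr(>F)"]][1], tolerance = 1e-9)
  }
})

test_that("ANOVA F is location-invariant and scale-invariant", {
  m <- c(3.41, 2.73, 3.20); s <- c(0.21, 0.23, 0.52); n <- c(5, 5, 5)
  f0 <- anovaOnewayFromSummary(m, s, n)$F
  expect_equal(anovaOnewayFromSummary(m + 100, s, n)$F, f0)
  expect_equal(anovaOnewayFromSummary(10 * m, 10 * s, n)$F, f0)
  expect_equal(anovaOnewayFromSummary(c(2, 2, 2), s, n)$F, 0)
  expect_equal(anovaOnewayFromSummary(c(2, 2, 2), s, n)$p, 1)
  expect_error(anovaOnewayFromSummary(m, c(0, 0, 0), n), "variance")
})

test_that("Tukey HSD from summaries flags the separated pair", {
  m <- c(3.41, 2.73, 3.20); s <- c(0.21, 0.23, 0.52); n <- c(5, 5, 5)
  hsd <- tukeyHsdFromSummary(m, s, n)
  expect_equal(nrow(hsd), 3)
  ## group 1 vs 2 is the extreme difference: smallest adjusted p
  expect_equal(which.min(hsd$pAdj), 1)
  expect_true(all(hsd$pAdj > 0 & hsd$pAdj <= 1))
})

test_that("clump-statistic comparison runs one exact test per statistic", {
  mkClumps <- function(sizes) {
    clumps <- lapply(seq_along(sizes), function(i)
      cbind(x = seq_len(sizes[i]) - 1L, y = 3L * i))
    new("ClumpSet", clumps = clumps, connectivity = "8-neighbor",
        gridDim = c(100L, 100L))
  }
  a <- lapply(c(10, 11, 12, 13, 14), function(n) mkClumps(rep(2, n)))
  b <- lapply(c(1, 2, 3, 4, 5), function(n) mkClumps(rep(9, n)))
  res <- compareClumpStats(a, b)
  expect_equal(pValue(res$count), 2 / 252, tolerance = 1e-12)
  expect_equal(pValue(res$medianSize), 2 / 252, tolerance = 1e-12)
  same <- compareClumpStats(a, a)
  expect_equal(pValue(same$count), 1)
  expect_error(compareClumpStats(a[1], b), "at least 2")
})

test_that("distance-bin comparison tests each 3 mm bin separately", {
  mkProfile <- function(fracs) {
    counts <- as.integer(round(fracs * 100))
    new("DistanceProfile", perPixelMm = rep(1, 100),
        binEdgesMm = c(0, 3, 6, 9, 12), binCounts = counts,
        binFractions = fracs, nTotal = 100L, nOutside = 0L)
  }
  a <- lapply(seq(0.88, 0.92, by = 0.01), function(f)
    mkProfile(c(f, 1 - f, 0, 0)))
  b <- lapply(seq(0.08, 0.12, by = 0.01), function(f)
    mkProfile(c(f, 1 - f, 0, 0)))
  res <- compareDistanceBins(a, b)
  expect_length(res, 4)
  expect_equal(pValue(res[["0-3"]]), 2 / 252, tolerance = 1e-12)
  expect_equal(pValue(res[["3-6"]]), 2 / 252, tolerance = 1e-12)
  ## identical sets: all p = 1
  expect_true(all(vapply(compareDistanceBins(a, a), pValue,
                         numeric(1)) == 1))
  bad <- list(new("DistanceProfile", perPixelMm = numeric(0),
                  binEdgesMm = c(0, 5, 10), binCounts = c(0L, 0L),
                  binFractions = c(NaN, NaN), nTotal = 0L, nOutside = 0L))
  expect_error(compareDistanceBins(a, bad), "bin edges")
})
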