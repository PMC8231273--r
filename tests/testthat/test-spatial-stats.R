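test_that("z-scoring centers and scales the on-tissue values", {
  img <- makeImage(matrix(c(1, 2, 3, 99), 1, 4))
  msk <- makeMask(matrix(c(TRUE, TRUE, TRUE, FALSE), 1, 4))
  z <- zscoreSection(img, msk)
  expect_equal(as.vector(intensityValues(z)[1, 1:3]), c(-1, 0, 1))
  expect_true(is.na(intensityValues(z)[1, 4]))
  expect_equal(z@scaleType, "zscore")
  ## contract: mean 0, sd 1
  withr::local_seed(31)
  v <- matrix(runif(60), 6, 10)
  z2 <- intensityValues(zscoreSection(makeImage(v),
                                      makeMask(matrix(TRUE, 6, 10))))
  expect_equal(mean(z2), 0, tolerance = 1e-9)
  expect_equal(sd(as.vector(z2)), 1, tolerance = 1e-9)
  expect_error(zscoreSection(makeImage(matrix(5, 2, 2)),
                             makeMask(matrix(TRUE, 2, 2))), "constant")
})

test_that("quartile binning follows the ceiling rank rule with row-major ties", {
  msk <- makeMask(matrix(TRUE, 1, 8))
  q <- quartileBin(makeImage(matrix(as.numeric(1:8), 1, 8)), msk)
  expect_equal(as.vector(quartileLabels(q)), c(1, 1, 2, 2, 3, 3, 4, 4))
  ## n = 5: label of rank r is ceiling(4 r / 5) -> sizes 1,1,1,2
  q5 <- quartileBin(makeImage(matrix(c(10, 20, 30, 40, 50), 1, 5)),
                    makeMask(matrix(TRUE, 1, 5)))
  expect_equal(as.vector(quartileLabels(q5)), ceiling(4 * (1:5) / 5))
  expect_equal(tabulate(quartileLabels(q5), 4), c(1, 1, 1, 2))
  ## all-tied values: labels follow row-major order deterministically
  qt <- quartileBin(makeImage(matrix(7, 2, 4)), makeMask(matrix(TRUE, 2, 4)))
  expect_equal(as.vector(t(quartileLabels(qt))), c(1, 1, 2, 2, 3, 3, 4, 4))
  expect_error(quartileBin(makeImage(matrix(1:3, 1, 3)),
                           makeMask(matrix(TRUE, 1, 3))), "at least 4")
})

test_that("quartile classes partition the tissue with sizes differing by <= 1", {
  withr::local_seed(32)
  for (rep in 1:20) {
    nr <- sample(2:9, 1); nc <- sample(2:9, 1)
    msk <- matrix(runif(nr * nc) < 0.7, nr, nc)
    if (sum(msk) < 4) next
    v <- matrix(sample(5, nr * nc, TRUE) + 0.0, nr, nc)  # heavy ties
    q <- quartileBin(makeImage(v), makeMask(msk))
    lab <- quartileLabels(q)
    expect_identical(is.na(lab), !msk)
    sizes <- tabulate(lab[msk], 4)
    expect_lte(max(sizes) - min(sizes), 1)
  }
})

test_that("binning depends only on ranks: z-scoring first changes nothing", {
  withr::local_seed(33)
  v <- matrix(rlnorm(80), 8, 10)
  msk <- makeMask(matrix(runif(80) < 0.8, 8, 10))
  img <- makeImage(v)
  q1 <- quartileBin(img, msk)
  q2 <- quartileBin(zscoreSection(img, msk), msk)
  expect_identical(quartileLabels(q1), quartileLabels(q2))
})

test_that("clump detection follows the declared adjacency rule", {
  lab <- matrix(NA_integer_, 6, 6)
  lab[cbind(c(1, 2, 6), c(1, 1, 6))] <- 4L  # (0,0),(0,1) adjacent, (5,5) apart
  qm <- new("QuartileMap", labels = lab, sourceSection = "t",
            pixelPitchUm = 400)
  cs <- findClumps(qm)
  expect_length(clumpPixels(cs), 2)
  expect_setequal(clumpSizes(cs), c(2, 1))
  ## diagonal pair: one clump under 8-neighbor, two under 4-neighbor
  lab2 <- matrix(NA_integer_, 3, 3)
  lab2[cbind(c(1, 2), c(1, 2))] <- 4L
  qm2 <- new("QuartileMap", labels = lab2, sourceSection = "t",
             pixelPitchUm = 400)
  expect_length(clumpPixels(findClumps(qm2, "8-neighbor")), 1)
  expect_length(clumpPixels(findClumps(qm2, "4-neighbor")), 2)
  ## no 4th-quartile pixels: empty set, summary (0, NA)
  lab3 <- matrix(c(1L, 2L, 3L, NA), 2, 2)
  qm3 <- new("QuartileMap", labels = lab3, sourceSection = "t",
             pixelPitchUm = 400)
  empty <- findClumps(qm3)
  expect_length(clumpPixels(empty), 0)
  expect_equal(clumpSummary(empty), list(count = 0,
                                         medianSizePx = NA_real_))
})

test_that("clump summaries give count and median size", {
  mk <- function(sizes) {
    ## lay clumps on well-separated rows
    clumps <- lapply(seq_along(sizes), function(i)
      cbind(x = seq_len(sizes[i]) - 1L, y = 3L * i))
    new("ClumpSet", clumps = clumps, connectivity = "8-neighbor",
        gridDim = c(100L, 100L))
  }
  expect_equal(clumpSummary(mk(c(2, 1))), list(count = 2, medianSizePx = 1.5))
  expect_equal(clumpSummary(mk(5)), list(count = 1, medianSizePx = 5))
})

test_that("clump sizes always sum to the number of 4th-quartile pixels", {
  withr::local_seed(34)
  for (rep in 1:10) {
    msk <- matrix(runif(100) < 0.6, 10, 10)
    if (sum(msk) < 4) next
    qm <- quartileBin(makeImage(matrix(rlnorm(100), 10, 10)),
                      makeMask(msk))
    lab <- quartileLabels(qm)
    for (conn in c("8-neighbor", "4-neighbor")) {
      cs <- findClumps(qm, conn)
      expect_equal(sum(clumpSizes(cs)), sum(lab == 4L, na.rm = TRUE))
    }
  }
})

test_that("connected components agree with a flood-fill oracle on random grids", {
  withr::local_seed(35)
  for (rep in 1:60) {
    nr <- sample(2:12, 1); nc <- sample(2:12, 1)
    fg <- matrix(runif(nr * nc) < runif(1, 0.2, 0.8), nr, nc)
    for (conn in c("8-neighbor", "4-neighbor")) {
      got <- msiSpatial:::.labelComponents(fg, conn)
      want <- floodFillLabels(fg, conn)
      expect_identical(componentSignature(got), componentSignature(want))
    }
  }
})

test_that("the alpha hull reduces to the convex hull for large alpha", {
  withr::local_seed(36)
  msk <- maskMatrix(generateTissueMask(GeneratorParams("dispersed",
                                                       seed = 3)))
  tm <- makeMask(msk)
  b <- alphaHullBorder(tm, alphaMm = 1e6)
  pts <- msiSpatial:::.pixelCentersMm(msiSpatial:::.maskCoords(msk), 400)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  ring <- borderRings(b)[[1]]
  expect_equal(nrow(ring), nrow(hull))
  ## same vertex set within 1e-9 mm
  ord <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]
  expect_equal(unname(ord(ring)), unname(ord(hull)), tolerance = 1e-9)
})

test_that("a filled rectangle's border is exactly its outer pixel centers", {
  msk <- matrix(FALSE, 12, 14)
  msk[3:10, 4:11] <- TRUE
  b <- alphaHullBorder(makeMask(msk), alphaMm = 1.2)
  ring <- borderRings(b)[[1]]
  perim <- msk
  perim[4:9, 5:10] <- FALSE  # interior removed
  want <- msiSpatial:::.pixelCentersMm(msiSpatial:::.maskCoords(perim), 400)
  ord <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]
  expect_equal(unname(ord(ring)), unname(ord(want)), tolerance = 1e-9)
})

test_that("a C-shaped mask's alpha hull enters the notch", {
  msk <- matrix(FALSE, 20, 20)
  msk[3:18, 3:18] <- TRUE
  msk[8:13, 9:18] <- FALSE  # notch opening to the right
  tm <- makeMask(msk)
  b <- alphaHullBorder(tm, alphaMm = 0.8)  # about 2 x pitch
  ringLen <- function(r) {
    k <- nrow(r); sum(sqrt(rowSums((r - r[c(2:k, 1), ])^2)))
  }
  pts <- msiSpatial:::.pixelCentersMm(msiSpatial:::.maskCoords(msk), 400)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  expect_gt(sum(vapply(borderRings(b), ringLen, numeric(1))),
            ringLen(hull))
})

test_that("alpha hull rejects degenerate inputs", {
  expect_error(alphaHullBorder(makeMask(matrix(TRUE, 3, 1))), "collinear")
  expect_error(alphaHullBorder(makeMask(matrix(c(TRUE, TRUE, TRUE, FALSE),
                                               2, 2)), alphaMm = 0.1),
               "pixel pitch")
})

test_that("distance profile: center of a 10 mm square is 5 mm from the border", {
  msk <- matrix(FALSE, 29, 29)
  msk[3:27, 3:27] <- TRUE  # 25 x 25 px = 10 x 10 mm at 400 um
  tm <- makeMask(msk)
  b <- alphaHullBorder(tm, alphaMm = 1.2)
  center <- cbind(x = 14L, y = 14L)  # 0-based center pixel
  pr <- distanceProfile(center, b, 400, binEdgesMm = c(0, 3, 6))
  expect_lte(abs(pr@perPixelMm - 5), 0.2 + 1e-9)  # within half a pitch
  ## a pixel on the ring has distance <= one pitch
  onRing <- cbind(x = 2L, y = 10L)
  pr2 <- distanceProfile(onRing, b, 400, binEdgesMm = c(0, 3))
  expect_lte(pr2@perPixelMm, 0.4 + 1e-9)
})

test_that("distances bin into half-open 3 mm intervals", {
  ## tall rectangle so the left edge is the nearest border for all probes
  msk <- matrix(FALSE, 70, 60)
  msk[3:68, 3:58] <- TRUE
  b <- alphaHullBorder(makeMask(msk), alphaMm = 1.2)
  ## pixels near 0.5, 3.5, 7.0, 10.0 mm from the left border (y centered)
  offs <- c(0.5, 3.5, 7.0, 10.0)
  px <- cbind(x = as.integer(2 + round(offs / 0.4)), y = 35L)
  pr <- distanceProfile(px, b, 400)
  expect_equal(pr@binCounts, rep(1L, 4))
  expect_equal(pr@binFractions, rep(0.25, 4))
  expect_equal(pr@nTotal, 4L)
})

test_that("distance profiles are invariant under translation of the section", {
  base <- matrix(FALSE, 30, 40)
  base[5:20, 5:25] <- TRUE
  base[10:15, 20:25] <- FALSE
  shifted <- matrix(FALSE, 30, 40)
  shifted[9:24, 12:32] <- TRUE
  shifted[14:19, 27:32] <- FALSE
  q4 <- cbind(x = c(8L, 12L, 16L), y = c(7L, 10L, 14L))
  prA <- distanceProfile(q4, alphaHullBorder(makeMask(base), 1.2), 400)
  prB <- distanceProfile(q4 + rep(c(7L, 4L), each = 3),
                         alphaHullBorder(makeMask(shifted), 1.2), 400)
  expect_equal(prA@perPixelMm, prB@perPixelMm, tolerance = 1e-9)
})

test_that("every tissue pixel lies inside or on the default-alpha border", {
  s <- generateTissueMask(GeneratorParams("dispersed", seed = 9))
  b <- alphaHullBorder(s)
  pts <- msiSpatial:::.pixelCentersMm(
    msiSpatial:::.maskCoords(maskMatrix(s)), 400)
  bnd <- do.call(rbind, lapply(borderRings(b), function(r)
    rbind(r, c(NA, NA))))
  inside <- mgcv::in.out(bnd, pts)
  dmin <- rep(Inf, nrow(pts))
  for (r in borderRings(b))
    dmin <- pmin(dmin, msiSpatial:::.distToRing(pts, r))
  expect_true(all(inside | dmin <= 1e-9))
})

test_that("colocalization is a rank correlation with the expected limits", {
  withr::local_seed(37)
  v <- matrix(rlnorm(48), 6, 8)
  msk <- makeMask(matrix(TRUE, 6, 8))
  a <- makeImage(v)
  expect_equal(colocalizationScore(a, a, msk), 1)
  ## reversed ranks (shifted to stay non-negative)
  b <- makeImage(max(v) + 1 - v)
  expect_equal(colocalizationScore(a, b, msk), -1)
  expect_error(colocalizationScore(a, makeImage(matrix(1, 6, 8)), msk),
               "constant")
  ## generator ground truth: full coupling, zero noise
  s <- generateSection(GeneratorParams("dispersed", seed = 4, noiseCv = 0,
                                       spcCoupling = 1))
  reg <- ionTargetRegistry()
  bud <- extractIonImage(s$budesonide, reg$budesonide)
  spc <- extractIonImage(s$spc, reg$spc)
  msk2 <- tissueMaskFromHeme(extractIonImage(s$budesonide, reg$heme))
  expect_equal(colocalizationScore(bud, spc, msk2), 1)
})
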