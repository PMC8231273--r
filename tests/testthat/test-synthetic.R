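test_that("tissue masks are reproducible, connected, non-convex and mid-sized", {
  p <- GeneratorParams("dispersed", seed = 1)
  m1 <- generateTissueMask(p)
  m2 <- generateTissueMask(p)
  expect_identical(maskMatrix(m1), maskMatrix(m2))
  ## connectivity and fill fraction across many seeds
  fills <- vapply(1:100, function(sd) {
    m <- maskMatrix(generateTissueMask(GeneratorParams("dispersed",
                                                       seed = sd)))
    lab <- floodFillLabels(m)
    expect_equal(max(lab, na.rm = TRUE), 1)
    mean(m)
  }, numeric(1))
  expect_true(all(fills >= 0.3 & fills <= 0.8))
  ## non-convex: some pixel center inside the convex hull is off-mask
  m <- maskMatrix(m1)
  pts <- msiSpatial:::.pixelCentersMm(msiSpatial:::.maskCoords(m), 400)
  hull <- pts[grDevices::chull(pts), ]
  off <- msiSpatial:::.pixelCentersMm(msiSpatial:::.maskCoords(!m), 400)
  insideHull <- mgcv::in.out(rbind(hull, c(NA, NA)), off)
  expect_gt(sum(insideHull), 0)
  expect_error(generateTissueMask(GeneratorParams("dispersed",
                                                  gridShape = c(3L, 3L))),
               "4 x 4")
})

test_that("identical parameters and seed give bit-identical sections", {
  p <- GeneratorParams("clumpy", seed = 8)
  s1 <- generateSection(p)
  s2 <- generateSection(p)
  expect_identical(spectra(s1$budesonide), spectra(s2$budesonide))
  expect_identical(spectra(s1$spc), spectra(s2$spc))
  ## and byte-identical serialized imzML
  tmp <- withr::local_tempdir()
  writeImzML(s1$budesonide, file.path(tmp, "a"))
  writeImzML(s2$budesonide, file.path(tmp, "b"))
  expect_identical(unname(tools::md5sum(file.path(tmp, "a.ibd"))),
                   unname(tools::md5sum(file.path(tmp, "b.ibd"))))
})

test_that("control sections carry only chemical background in the drug window", {
  reg <- ionTargetRegistry()
  s <- generateSection(GeneratorParams("control", seed = 3))
  img <- extractIonImage(s$budesonide, reg$budesonide)
  v <- intensityValues(img)[maskMatrix(s$truth$mask)]
  ## background scale: a few percent of the base intensity, never signal-like
  expect_lt(max(v), 0.35 * 1000)
  expect_gt(mean(v > 0), 0.99)
  ## requesting a control with a nonzero drug amplitude is a config error
  expect_error(GeneratorParams("control", budAmplitude = 500),
               "control sections")
})

test_that("a cleared section is its matched dispersed section at 7% intensity", {
  reg <- ionTargetRegistry()
  d <- generateSection(GeneratorParams("dispersed", seed = 21))
  cl <- generateSection(GeneratorParams("cleared", seed = 21,
                                        clearanceFraction = 0.93))
  totD <- sum(intensityValues(extractIonImage(d$budesonide,
                                              reg$budesonide)))
  totC <- sum(intensityValues(extractIonImage(cl$budesonide,
                                              reg$budesonide)))
  expect_equal(totC / totD, 0.07, tolerance = 1e-6)
})

test_that("cleared sections lose >90% of above-threshold pixels", {
  reg <- ionTargetRegistry()
  norm <- function(s) {
    bud <- extractIonImage(s$budesonide, reg$budesonide)
    isI <- extractIonImage(s$budesonide, reg$internal_standard)
    msk <- tissueMaskFromHeme(extractIonImage(s$budesonide, reg$heme))
    list(img = normalizeImage(bud, isI), msk = msk)
  }
  for (sd in c(31, 32)) {
    d <- norm(generateSection(GeneratorParams("dispersed", seed = sd)))
    cl <- norm(generateSection(GeneratorParams("cleared", seed = sd)))
    c1 <- norm(generateSection(GeneratorParams("control", seed = 500 + sd)))
    c2 <- norm(generateSection(GeneratorParams("control", seed = 900 + sd)))
    thr <- controlThreshold(list(c1$img, c2$img), list(c1$msk, c2$msk))
    nAbove <- function(a)
      sum(!is.na(intensityValues(aboveThresholdMap(a$img, a$msk, thr))))
    expect_lt(nAbove(cl), 0.1 * nAbove(d))
  }
})

test_that("SP-C tracks the drug field perfectly at full coupling, zero noise", {
  reg <- ionTargetRegistry()
  s <- generateSection(GeneratorParams("dispersed", seed = 13, noiseCv = 0,
                                       spcCoupling = 1))
  bud <- extractIonImage(s$budesonide, reg$budesonide)
  spc <- extractIonImage(s$spc, reg$spc)
  msk <- tissueMaskFromHeme(extractIonImage(s$budesonide, reg$heme))
  sel <- maskMatrix(msk)
  expect_equal(cor(intensityValues(bud)[sel], intensityValues(spc)[sel],
                   method = "spearman"), 1)
})

test_that("cohorts have the study layout with distinct derived seeds", {
  co <- generateCohort(1, seed = 2)
  expect_length(co$sections, 5)           # 1+1+1+2
  expect_equal(sort(unique(co$manifest$group)),
               c("cleared", "clumpy", "control", "dispersed"))
  expect_equal(sum(co$manifest$group == "control"), 2)
  expect_false(anyDuplicated(co$manifest$seed) > 0)
  expect_error(generateCohort(0), "nPerGroup")
  ## the n = 5 study design gives 17 sections; check the bookkeeping only
  groups <- c(rep(c("clumpy", "dispersed", "cleared"), each = 5),
              rep("control", 2))
  expect_length(groups, 17)
})

test_that("dispersed cohorts show more, smaller clumps than clumpy cohorts", {
  ## parameter-recovery property across independently seeded cohorts
  nCohorts <- 20
  perGroup <- 3
  withr::local_seed(41)
  seeds <- matrix(sample.int(1e6, nCohorts * perGroup * 2),
                  ncol = 2 * perGroup)
  for (k in seq_len(nCohorts)) {
    disp <- lapply(seeds[k, 1:perGroup], function(sd)
      sectionClumpStats(generateSection(GeneratorParams("dispersed",
                                                        seed = sd))))
    clum <- lapply(seeds[k, perGroup + 1:perGroup], function(sd)
      sectionClumpStats(generateSection(GeneratorParams("clumpy",
                                                        seed = sd))))
    meanCount <- function(g) mean(vapply(g, function(x)
      x$summary$count, numeric(1)))
    medSize <- function(g) stats::median(vapply(g, function(x)
      x$summary$medianSizePx, numeric(1)))
    expect_gt(meanCount(disp), meanCount(clum))
    expect_lt(medSize(disp), medSize(clum))
  }
})
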