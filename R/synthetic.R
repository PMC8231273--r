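## Seeded synthetic MSI cohorts with the spatial and statistical structure
## the analysis assumes: irregular connected lung-lobe masks, a heme channel
## on tissue only, a uniform internal-standard channel, a budesonide channel
## following a clumpy / dispersed / cleared / control pattern, and a
## companion SP-C dataset spatially coupled to the budesonide field.
##
## Intensity model: sum of isotropic Gaussian foci on the tissue mask,
## multiplied by log-normal pixel noise, plus an additive gamma-distributed
## chemical background at each registered m/z (every channel of a real
## section sits on a nonzero chemical background; the control violin
## distribution and the control-derived detection threshold both live on
## it). The multiplicative noise has two components: a per-pixel
## acquisition-efficiency factor with the stated CV, shared by all channels
## of a dataset (spray and matrix heterogeneity are common-mode across ions
## -- the reason internal-standard normalization works at all), and a
## smaller channel-specific residual (CV / 6) that survives normalization.
## Focus centers are drawn with peripheral bias: with probability
## `peripheralBias` a center is sampled with weight exp(-d/lambda), lambda =
## 2 mm, where d is the distance to the tissue border; otherwise with weight
## proportional to d (interior preference).

.PERIPHERAL_LAMBDA_MM <- 2
## chemical background, as a fraction of baseIntensity, per channel window
.BG_FRACTION <- c(budesonide = 0.06, internal_standard = 0.03,
                  heme = 0.003, spc = 0.03)
.SPC_AMPLITUDE <- 0.1     # SP-C peak scale relative to baseIntensity
.NOISE_PEAK_RATE <- 4     # mean sparse chemical-noise peaks per pixel
.NOISE_PEAK_FRACTION <- 0.001

#' Generate an irregular tissue mask
#'
#' A single connected, non-convex region emulating a transverse lung-lobe
#' outline: a randomly modulated ellipse with a disk-shaped "bite" removed
#' at the boundary (guaranteeing at least one concavity). For the default
#' grid the mask covers roughly half of the raster; the construction keeps
#' the covered fraction within 30-80\% of the grid across seeds.
#'
#' @param params a \linkS4class{GeneratorParams}; only the grid shape, pitch
#'   and seed are used.
#' @return A \linkS4class{TissueMask} (source \code{"truth"}).
#' @export
generateTissueMask <- function(params) {
  validObject(params)
  nr <- params@gridShape[1L]; nc <- params@gridShape[2L]
  if (nr < 4L || nc < 4L)
    stop(sprintf("grid %d x %d is too small: need at least 4 x 4 pixels",
                 nr, nc))
  set.seed(params@seed)
  .makeMaskNoSeed(nr, nc, params@pixelPitchUm)
}

## Mask construction using the current RNG state.
.makeMaskNoSeed <- function(nr, nc, pitchUm) {
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  a <- 0.44 * nc; b <- 0.42 * nr
  a1 <- stats::runif(1, 0.04, 0.09); ph1 <- stats::runif(1, 0, 2 * pi)
  a2 <- stats::runif(1, 0.03, 0.06); ph2 <- stats::runif(1, 0, 2 * pi)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  row <- matrix(seq_len(nr), nr, nc)
  ex <- (col - cx) / a; ey <- (row - cy) / b
  theta <- atan2(ey, ex)
  s <- 1 + a1 * sin(2 * theta + ph1) + a2 * sin(3 * theta + ph2)
  fg <- (ex^2 + ey^2) <= s^2
  ## concave bite at a random boundary angle
  tb <- stats::runif(1, 0, 2 * pi)
  sb <- 1 + a1 * sin(2 * tb + ph1) + a2 * sin(3 * tb + ph2)
  bx <- cx + a * sb * cos(tb); by <- cy + b * sb * sin(tb)
  rb <- stats::runif(1, 0.28, 0.38) * b
  fg <- fg & ((col - bx)^2 + (row - by)^2 > rb^2)
  ## keep the largest connected component
  lab <- .labelComponents(fg, "8-neighbor")
  if (any(fg)) {
    sizes <- tabulate(lab[!is.na(lab)])
    fg <- !is.na(lab) & lab == which.max(sizes)
  }
  TissueMask(fg, source = "truth", pixelPitchUm = pitchUm)
}

## Sample k focus centers among tissue pixels with peripheral bias.
.sampleCenters <- function(k, dBorderMm, coordsMm, bias) {
  if (k == 0L) return(coordsMm[integer(0), , drop = FALSE])
  peripheral <- stats::runif(k) < bias
  wPeri <- exp(-dBorderMm / .PERIPHERAL_LAMBDA_MM)
  wCent <- dBorderMm + 0.1
  idx <- integer(k)
  for (i in seq_len(k)) {
    w <- if (peripheral[i]) wPeri else wCent
    idx[i] <- sample.int(length(dBorderMm), 1L, prob = w)
  }
  coordsMm[idx, , drop = FALSE]
}

## Gaussian focus field over pixel centers.
.blobField <- function(coordsMm, centers, sigmaMm, amplitude) {
  f <- numeric(nrow(coordsMm))
  for (i in seq_len(nrow(centers))) {
    d2 <- (coordsMm[, 1L] - centers[i, 1L])^2 +
      (coordsMm[, 2L] - centers[i, 2L])^2
    f <- f + amplitude * exp(-d2 / (2 * sigmaMm^2))
  }
  f
}

## Log-normal multiplicative noise with mean 1 and the given CV.
.lnNoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

## Sparse chemical-noise centroids for one dataset, avoiding the target
## windows so every channel stays identifiable. Returns parallel vectors.
.noisePeaks <- function(nPixels, mzRange, avoidMz, avoidTol, base) {
  counts <- stats::rpois(nPixels, .NOISE_PEAK_RATE)
  tot <- sum(counts)
  mz <- stats::runif(tot, mzRange[1L], mzRange[2L])
  for (k in seq_along(avoidMz)) {
    bad <- abs(mz - avoidMz[k]) <= 3 * avoidTol[k]
    while (any(bad)) {
      mz[bad] <- stats::runif(sum(bad), mzRange[1L], mzRange[2L])
      bad <- abs(mz - avoidMz[k]) <= 3 * avoidTol[k]
    }
  }
  list(mz = mz, intensity = .NOISE_PEAK_FRACTION * base * stats::rexp(tot),
       pixel = rep(seq_len(nPixels), counts))
}

## Assemble per-pixel centroid spectra from channel peak values plus sparse
## noise. channels: list of list(mz =, values = numeric(nPixels)).
.assembleSpectra <- function(nPixels, channels, noise) {
  chMz <- vapply(channels, `[[`, numeric(1), "mz")
  chVal <- do.call(cbind, lapply(channels, `[[`, "values"))
  noiseIdx <- if (length(noise))
    split(seq_along(noise$pixel), factor(noise$pixel,
                                         levels = seq_len(nPixels)))
  else NULL
  lapply(seq_len(nPixels), function(i) {
    v <- chVal[i, ]
    keep <- v > 0
    mz <- chMz[keep]; int <- v[keep]
    if (!is.null(noiseIdx)) {
      j <- noiseIdx[[i]]
      if (length(j)) {
        mz <- c(mz, noise$mz[j]); int <- c(int, noise$intensity[j])
      }
    }
    o <- order(mz)
    list(mz = mz[o], intensity = int[o])
  })
}

#' Generate one synthetic lung section (budesonide + companion SP-C dataset)
#'
#' Produces the budesonide-acquisition dataset (m/z 185-650; heme, internal
#' standard and budesonide channels) and the companion SP-C dataset
#' (m/z 2000-5000) for the same tissue geometry, emulating two consecutive
#' 20 um sections of the same lobe. The budesonide channel follows
#' \code{params@pattern}; a cleared section is the matched dispersed section
#' whose entire budesonide window (signal and its chemical background) is
#' attenuated by \code{clearanceFraction}. SP-C carries signal only for the
#' surfactant-treated patterns (dispersed, cleared, control), coupled to the
#' budesonide field by \code{spcCoupling} where budesonide is present.
#'
#' @param params a \linkS4class{GeneratorParams}.
#' @param sectionId,groupLabel identifiers stored in the datasets; the group
#'   label defaults to the pattern name.
#' @return \code{list(budesonide = MSIDataset, spc = MSIDataset, truth =
#'   list(mask, budField, spcField))} where \code{truth} holds the
#'   generator's ground truth for validation.
#' @export
generateSection <- function(params, sectionId = sprintf("%s_s%d",
                                                        params@pattern,
                                                        params@seed),
                            groupLabel = params@pattern) {
  validObject(params)
  nr <- params@gridShape[1L]; nc <- params@gridShape[2L]
  if (nr < 4L || nc < 4L)
    stop(sprintf("grid %d x %d is too small: need at least 4 x 4 pixels",
                 nr, nc))
  base <- params@baseIntensity
  cv <- params@noiseCv
  pitchMm <- params@pixelPitchUm / 1000
  reg <- ionTargetRegistry()

  set.seed(params@seed)
  mask <- .makeMaskNoSeed(nr, nc, params@pixelPitchUm)
  fg <- mask@onTissue
  nPix <- nr * nc
  ## all grid pixels are acquired (the instrument rasters the whole slide)
  allCoords <- .maskCoords(matrix(TRUE, nr, nc))
  onTissue <- fg[cbind(allCoords[, 2L] + 1L, allCoords[, 1L] + 1L)]
  centersMm <- .pixelCentersMm(allCoords, params@pixelPitchUm)

  dPx <- .borderDistancePx(fg)
  dBorderMm <- dPx[cbind(allCoords[onTissue, 2L] + 1L,
                         allCoords[onTissue, 1L] + 1L)] * pitchMm
  tissueMm <- centersMm[onTissue, , drop = FALSE]

  ## budesonide focus field (zero for control)
  amp <- if (!is.na(params@budAmplitude)) params@budAmplitude else base
  budField <- numeric(nPix)
  if (params@pattern != "control" && params@nBlobs > 0L) {
    ctr <- .sampleCenters(params@nBlobs, dBorderMm, tissueMm,
                          params@peripheralBias)
    budField[onTissue] <- .blobField(tissueMm, ctr, params@blobSigmaMm, amp)
  }
  ## smooth heme morphology field, rescaled to [0.75, 1.25]
  hemeCtr <- .sampleCenters(5L, dBorderMm, tissueMm, 0)
  hemeRaw <- .blobField(tissueMm, hemeCtr, 4, 1)
  hemeRel <- if (diff(range(hemeRaw)) > 0)
    0.75 + 0.5 * (hemeRaw - min(hemeRaw)) / diff(range(hemeRaw)) else
      rep(1, length(hemeRaw))
  ## independent field for the SP-C channel's uncoupled share
  spcCtr <- .sampleCenters(8L, dBorderMm, tissueMm, 0.5)
  spcRaw <- .blobField(tissueMm, spcCtr, 2, 1)

  ## chemical background at a registered m/z: gamma with shape 16 (a sum
  ## of many small matrix-cluster contributions, hence mildly dispersed),
  ## mean .BG_FRACTION * base
  bg <- function(channel, n) {
    if (cv == 0) return(numeric(n))
    .BG_FRACTION[[channel]] * base * stats::rgamma(n, shape = 16, rate = 16)
  }
  resCv <- cv / 6  # channel-specific residual after common-mode factor

  ## per-pixel acquisition-efficiency factor, common to all channels of the
  ## budesonide acquisition (cancels under internal-standard normalization)
  mu <- .lnNoise(nPix, cv)

  ## budesonide channel: everywhere on the grid (background included);
  ## a cleared section is the matched 1-min section with its whole
  ## budesonide window attenuated by the clearance fraction
  budChannel <- mu * (budField * .lnNoise(nPix, resCv) +
                        bg("budesonide", nPix))
  if (params@pattern == "cleared")
    budChannel <- budChannel * (1 - params@clearanceFraction)

  nOn <- sum(onTissue)
  hemeChannel <- numeric(nPix)
  hemeChannel[onTissue] <- mu[onTissue] *
    (base * hemeRel * .lnNoise(nOn, resCv) + bg("heme", nOn))
  isChannel <- numeric(nPix)
  isChannel[onTissue] <- mu[onTissue] * base * .lnNoise(nOn, resCv)

  ## SP-C channel: coupled to the budesonide field for surfactant groups
  spcField <- numeric(nPix)
  surfactant <- params@pattern %in% c("dispersed", "cleared", "control")
  if (surfactant) {
    couple <- if (params@pattern == "control") 0 else params@spcCoupling
    budNorm <- if (max(budField) > 0) budField[onTissue] / max(budField)
               else numeric(sum(onTissue))
    spcNorm <- if (max(spcRaw) > 0) spcRaw / max(spcRaw) else spcRaw
    mix <- couple * budNorm + (1 - couple) * spcNorm
    spcField[onTissue] <- .SPC_AMPLITUDE * base * mix
  }
  ## the SP-C acquisition is a separate (consecutive) section and prep, so
  ## it carries its own acquisition-efficiency factor
  muSpc <- .lnNoise(nPix, cv)
  spcChannel <- muSpc * spcField * .lnNoise(nPix, resCv)
  spcChannel[onTissue] <- spcChannel[onTissue] +
    muSpc[onTissue] * bg("spc", nOn)

  mzBud <- c(185, 650); mzSpc <- c(2000, 5000)
  noiseBud <- if (cv > 0)
    .noisePeaks(nPix, mzBud,
                c(reg$budesonide@targetMz, reg$internal_standard@targetMz,
                  reg$heme@targetMz),
                c(reg$budesonide@toleranceDa,
                  reg$internal_standard@toleranceDa, reg$heme@toleranceDa),
                base) else list()
  noiseSpc <- if (cv > 0)
    .noisePeaks(nPix, mzSpc, reg$spc@targetMz, reg$spc@toleranceDa, base)
    else list()

  budSpectra <- .assembleSpectra(nPix, list(
    list(mz = reg$budesonide@targetMz, values = budChannel),
    list(mz = reg$internal_standard@targetMz, values = isChannel),
    list(mz = reg$heme@targetMz, values = hemeChannel)), noiseBud)
  spcSpectra <- .assembleSpectra(nPix, list(
    list(mz = reg$spc@targetMz, values = spcChannel)), noiseSpc)

  budDs <- MSIDataset(budSpectra, allCoords, c(nr, nc),
                      pixelPitchUm = params@pixelPitchUm, mzRange = mzBud,
                      sectionId = sectionId, groupLabel = groupLabel)
  spcDs <- MSIDataset(spcSpectra, allCoords, c(nr, nc),
                      pixelPitchUm = params@pixelPitchUm, mzRange = mzSpc,
                      sectionId = paste0(sectionId, "_spc"),
                      groupLabel = groupLabel)
  budTruth <- matrix(0, nr, nc)
  budTruth[cbind(allCoords[, 2L] + 1L, allCoords[, 1L] + 1L)] <- budField
  spcTruth <- matrix(0, nr, nc)
  spcTruth[cbind(allCoords[, 2L] + 1L, allCoords[, 1L] + 1L)] <- spcField
  list(budesonide = budDs, spc = spcDs,
       truth = list(mask = mask, budField = budTruth, spcField = spcTruth))
}

#' Generate a full synthetic cohort
#'
#' \code{nPerGroup} sections for each of the clumpy (drug with saline
#' vehicle), dispersed (drug with surfactant) and cleared (drug with
#' surfactant, two hours of ventilation) patterns, plus two budesonide-free
#' control sections, each with a distinct seed derived from \code{seed}.
#'
#' @param nPerGroup sections per treated group (>= 1; the study design used
#'   5).
#' @param seed master seed from which per-section seeds are derived.
#' @param params a template \linkS4class{GeneratorParams} supplying the
#'   pattern-independent settings (grid, pitch, base intensity, noise CV,
#'   clearance fraction, SP-C coupling); the focus geometry of each section
#'   comes from its own pattern's defaults.
#' @return \code{list(sections = named list of generateSection outputs,
#'   manifest = data.frame(sectionId, group, seed))}.
#' @export
generateCohort <- function(nPerGroup, seed = 1L,
                           params = GeneratorParams("dispersed")) {
  if (nPerGroup < 1L) stop("nPerGroup must be >= 1")
  groups <- c(rep("clumpy", nPerGroup), rep("dispersed", nPerGroup),
              rep("cleared", nPerGroup), rep("control", 2L))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(groups))
  sections <- vector("list", length(groups))
  ids <- character(length(groups))
  for (i in seq_along(groups)) {
    p <- GeneratorParams(pattern = groups[i],
                         gridShape = params@gridShape,
                         pixelPitchUm = params@pixelPitchUm,
                         baseIntensity = params@baseIntensity,
                         noiseCv = params@noiseCv,
                         clearanceFraction = params@clearanceFraction,
                         spcCoupling = params@spcCoupling,
                         seed = seeds[i])
    within <- sum(groups[seq_len(i)] == groups[i])
    ids[i] <- sprintf("%s_%02d", groups[i], within)
    sections[[i]] <- generateSection(p, sectionId = ids[i],
                                     groupLabel = groups[i])
  }
  names(sections) <- ids
  list(sections = sections,
       manifest = data.frame(sectionId = ids, group = groups, seed = seeds,
                             stringsAsFactors = FALSE))
}
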