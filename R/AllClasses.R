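#' @import methods
NULL

## ---------------------------------------------------------------------------
## Ion targets
## ---------------------------------------------------------------------------

#' IonTarget: a registered ion to extract from centroid spectra
#'
#' An ion target is a named m/z value with an extraction tolerance and,
#' optionally, an elemental formula (plus charge) used to cross-check the
#' registered m/z against the computed monoisotopic mass.
#'
#' @slot name single character, e.g. \code{"heme"}.
#' @slot targetMz target mass-to-charge (Da).
#' @slot toleranceDa half-width of the extraction window (Da), > 0.
#' @slot formula elemental formula (e.g. \code{"C34H32FeN4O4"}) or
#'   \code{NA_character_} when the target is stored as an opaque m/z.
#' @slot charge integer charge used for the formula cross-check (ignored when
#'   no formula is given).
#'
#' @export
setClass("IonTarget",
  representation(name = "character", targetMz = "numeric",
                 toleranceDa = "numeric", formula = "character",
                 charge = "numeric"),
  prototype(formula = NA_character_, charge = 1))

setValidity("IonTarget", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@targetMz) != 1L || !is.finite(object@targetMz) ||
      object@targetMz <= 0)
    msg <- c(msg, "'targetMz' must be a single positive number")
  if (length(object@toleranceDa) != 1L || !is.finite(object@toleranceDa) ||
      object@toleranceDa <= 0)
    msg <- c(msg, "'toleranceDa' must be > 0")
  if (!is.na(object@formula)) {
    m <- monoisotopicMass(object@formula, charge = object@charge)
    if (abs(m - object@targetMz) > 2 * object@toleranceDa)
      msg <- c(msg, sprintf(
        "formula %s (charge %+d) gives m/z %.4f, more than 2 tolerances from target %.4f",
        object@formula, as.integer(object@charge), m, object@targetMz))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an IonTarget
#'
#' @param name target name.
#' @param targetMz target m/z (Da).
#' @param toleranceDa extraction tolerance (Da).
#' @param formula optional elemental formula for validation.
#' @param charge charge state used with \code{formula}.
#' @return An \linkS4class{IonTarget}.
#' @examples
#' IonTarget("heme", 616.176, 0.005, formula = "C34H32FeN4O4", charge = 1)
#' @export
IonTarget <- function(name, targetMz, toleranceDa, formula = NA_character_,
                      charge = 1) {
  new("IonTarget", name = as.character(name), targetMz = as.numeric(targetMz),
      toleranceDa = as.numeric(toleranceDa),
      formula = as.character(formula), charge = as.numeric(charge))
}

## ---------------------------------------------------------------------------
## MSIDataset
## ---------------------------------------------------------------------------

#' MSIDataset: pixel-indexed centroid spectra on a regular grid
#'
#' The unit of I/O for the package: a set of centroid (peak-list) spectra,
#' one per acquired pixel, on a regular raster with a physical pixel pitch.
#' Pixel coordinates are 0-based \code{(x, y)} = (column, row); the imzML
#' files on disk use the 1-based imzML convention and conversion happens only
#' at the I/O boundary.
#'
#' @slot spectra list (one element per pixel, same order as \code{coords});
#'   each element is a \code{list(mz =, intensity =)} pair of equal-length
#'   numeric vectors with strictly increasing \code{mz} and non-negative
#'   intensities. Zero-length spectra are allowed.
#' @slot coords integer matrix (n x 2, columns \code{x}, \code{y}), 0-based.
#' @slot gridDim integer \code{c(nrow, ncol)} bounding grid.
#' @slot pixelPitchUm pixel pitch in micrometres (400 for this study design).
#' @slot mzRange numeric \code{c(low, high)} acquisition range (Da).
#' @slot polarity \code{"positive"}.
#' @slot sectionId,groupLabel identifiers carried through the pipeline.
#'
#' @export
setClass("MSIDataset",
  representation(spectra = "list", coords = "matrix", gridDim = "integer",
                 pixelPitchUm = "numeric", mzRange = "numeric",
                 polarity = "character", sectionId = "character",
                 groupLabel = "character"),
  prototype(polarity = "positive", groupLabel = ""))

setValidity("MSIDataset", function(object) {
  msg <- character()
  co <- object@coords
  if (!is.matrix(co) || ncol(co) != 2L)
    return("'coords' must be an n x 2 matrix")
  if (length(object@spectra) != nrow(co))
    return("'spectra' and 'coords' must have one entry per pixel")
  if (length(object@gridDim) != 2L || any(object@gridDim < 1L))
    return("'gridDim' must be two positive integers (nrow, ncol)")
  if (nrow(co)) {
    if (any(co < 0L) || any(co[, 1L] >= object@gridDim[2L]) ||
        any(co[, 2L] >= object@gridDim[1L]))
      msg <- c(msg, "pixel coordinates outside the declared bounding grid")
    if (anyDuplicated(co[, 1L] + object@gridDim[2L] * co[, 2L]))
      msg <- c(msg, "duplicate pixel coordinates")
  }
  if (length(object@mzRange) != 2L || diff(object@mzRange) <= 0)
    msg <- c(msg, "'mzRange' must be an increasing (low, high) pair")
  if (!identical(object@polarity, "positive"))
    msg <- c(msg, "'polarity' must be \"positive\"")
  bad <- .checkSpectra(object@spectra, object@mzRange)
  if (!is.na(bad)) msg <- c(msg, bad)
  if (length(msg)) msg else TRUE
})

## Fast scan of a spectra list; returns NA when fine, else a message.
.checkSpectra <- function(spectra, mzRange) {
  lo <- mzRange[1L] - 1e-9; hi <- mzRange[2L] + 1e-9
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    if (!is.list(s) || is.null(s$mz) || is.null(s$intensity))
      return(sprintf("spectrum %d is not a list(mz, intensity)", i))
    if (length(s$mz) != length(s$intensity))
      return(sprintf("spectrum %d: mz and intensity lengths differ", i))
    if (length(s$mz)) {
      if (is.unsorted(s$mz, strictly = TRUE))
        return(sprintf("spectrum %d: mz not strictly increasing", i))
      if (s$mz[1L] < lo || s$mz[length(s$mz)] > hi)
        return(sprintf("spectrum %d: peaks outside mzRange", i))
      if (any(s$intensity < 0) || any(!is.finite(s$intensity)))
        return(sprintf("spectrum %d: negative or non-finite intensity", i))
    }
  }
  NA_character_
}

#' Construct an MSIDataset
#'
#' @param spectra list of \code{list(mz, intensity)} peak lists.
#' @param coords integer n x 2 matrix of 0-based (x, y) pixel coordinates.
#' @param gridDim integer \code{c(nrow, ncol)}.
#' @param pixelPitchUm pixel pitch (micrometres).
#' @param mzRange numeric \code{c(low, high)} (Da).
#' @param sectionId,groupLabel identifiers.
#' @return An \linkS4class{MSIDataset}.
#' @export
MSIDataset <- function(spectra, coords, gridDim, pixelPitchUm = 400,
                       mzRange, sectionId = "section", groupLabel = "") {
  co <- matrix(as.integer(coords), ncol = 2L,
               dimnames = list(NULL, c("x", "y")))
  new("MSIDataset", spectra = spectra, coords = co,
      gridDim = as.integer(gridDim), pixelPitchUm = as.numeric(pixelPitchUm),
      mzRange = as.numeric(mzRange), sectionId = as.character(sectionId),
      groupLabel = as.character(groupLabel))
}

## ---------------------------------------------------------------------------
## IonImage / TissueMask
## ---------------------------------------------------------------------------

#' IonImage: a 2D intensity raster for one ion target
#'
#' Values are non-negative intensities (arbitrary units) on the acquisition
#' grid; pixels that were not acquired, were dropped during normalization, or
#' fall below a threshold are \code{NA} ("missing"), never zero, so that
#' statistics run over tissue pixels only. After per-section standardization
#' (\code{\link{zscoreSection}}) the raster is on the z-score scale and may be
#' negative; \code{scaleType} records which scale the raster is on.
#'
#' @slot values numeric matrix (gridDim), \code{NA} = missing.
#' @slot pixelPitchUm pixel pitch (micrometres).
#' @slot target the \linkS4class{IonTarget} the raster was extracted for.
#' @slot sectionId source section.
#' @slot scaleType \code{"intensity"} or \code{"zscore"}.
#' @slot dropTally number of pixels dropped on the way to this raster
#'   (e.g. zero-reference pixels during normalization).
#'
#' @export
setClass("IonImage",
  representation(values = "matrix", pixelPitchUm = "numeric",
                 target = "IonTarget", sectionId = "character",
                 scaleType = "character", dropTally = "integer"),
  prototype(scaleType = "intensity", dropTally = 0L))

setValidity("IonImage", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  fin <- v[!is.na(v)]
  if (any(!is.finite(fin)))
    msg <- c(msg, "non-finite intensity values (use NA for missing pixels)")
  if (identical(object@scaleType, "intensity") && any(fin < 0))
    msg <- c(msg, "negative intensities in an intensity-scale image")
  if (!object@scaleType %in% c("intensity", "zscore"))
    msg <- c(msg, "'scaleType' must be \"intensity\" or \"zscore\"")
  if (length(object@pixelPitchUm) != 1L || object@pixelPitchUm <= 0)
    msg <- c(msg, "'pixelPitchUm' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname IonImage-class
#' @param values,pixelPitchUm,target,sectionId,scaleType,dropTally see slots.
#' @return An \linkS4class{IonImage}.
#' @export
IonImage <- function(values, pixelPitchUm, target, sectionId = "section",
                     scaleType = "intensity", dropTally = 0L) {
  new("IonImage", values = values, pixelPitchUm = as.numeric(pixelPitchUm),
      target = target, sectionId = as.character(sectionId),
      scaleType = scaleType, dropTally = as.integer(dropTally))
}

#' TissueMask: on-tissue pixels derived from the heme channel
#'
#' @slot onTissue logical matrix, \code{TRUE} on tissue.
#' @slot source name of the marker channel the mask came from.
#' @slot pixelPitchUm pixel pitch (micrometres).
#' @export
setClass("TissueMask",
  representation(onTissue = "matrix", source = "character",
                 pixelPitchUm = "numeric"))

setValidity("TissueMask", function(object) {
  if (!is.logical(object@onTissue)) return("'onTissue' must be logical")
  if (anyNA(object@onTissue)) return("'onTissue' must not contain NA")
  TRUE
})

#' @rdname TissueMask-class
#' @param onTissue,source,pixelPitchUm see slots.
#' @return A \linkS4class{TissueMask}.
#' @export
TissueMask <- function(onTissue, source = "heme", pixelPitchUm = 400) {
  new("TissueMask", onTissue = onTissue, source = as.character(source),
      pixelPitchUm = as.numeric(pixelPitchUm))
}

## ---------------------------------------------------------------------------
## Spatial statistics containers
## ---------------------------------------------------------------------------

#' QuartileMap: per-tissue-pixel quartile labels
#'
#' Rank-based quartile labels in \{1, 2, 3, 4\} over on-tissue pixels
#' (\code{NA} off tissue). Rank r of n maps to label \code{ceiling(4 r / n)},
#' so the four classes partition the tissue with sizes differing by at most 1.
#'
#' @slot labels integer matrix with values 1..4 or NA.
#' @slot sourceSection section id.
#' @slot pixelPitchUm pixel pitch (micrometres).
#' @export
setClass("QuartileMap",
  representation(labels = "matrix", sourceSection = "character",
                 pixelPitchUm = "numeric"))

setValidity("QuartileMap", function(object) {
  lab <- object@labels[!is.na(object@labels)]
  if (length(lab) && (!all(lab %in% 1:4)))
    return("labels must be in 1..4 or NA")
  n <- length(lab)
  if (n >= 4L) {
    sizes <- tabulate(lab, 4L)
    if (max(sizes) - min(sizes) > 1L)
      return("quartile class sizes differ by more than 1")
  }
  TRUE
})

#' ClumpSet: connected components of 4th-quartile pixels
#'
#' High-intensity "clumps": maximal sets of mutually adjacent top-quartile
#' pixels under the declared connectivity. Clumps are pairwise disjoint and
#' their union is exactly the set of 4th-quartile pixels.
#'
#' @slot clumps list of integer matrices (k x 2, 0-based x,y pixel coords).
#' @slot connectivity \code{"8-neighbor"} or \code{"4-neighbor"}.
#' @slot gridDim integer \code{c(nrow, ncol)} of the source raster.
#' @export
setClass("ClumpSet",
  representation(clumps = "list", connectivity = "character",
                 gridDim = "integer"))

setValidity("ClumpSet", function(object) {
  if (!object@connectivity %in% c("8-neighbor", "4-neighbor"))
    return("connectivity must be \"8-neighbor\" or \"4-neighbor\"")
  if (length(object@clumps)) {
    all <- do.call(rbind, object@clumps)
    if (anyDuplicated(all[, 1L] + object@gridDim[2L] * all[, 2L]))
      return("clumps are not pairwise disjoint")
  }
  TRUE
})

#' BorderCurve: closed polyline(s) delineating the tissue, in mm
#'
#' One or more closed rings (vertex matrices in physical millimetres; the
#' last vertex connects back to the first implicitly) produced by the
#' alpha-shape of on-tissue pixel centers.
#'
#' @slot rings list of numeric matrices (k x 2, columns x_mm, y_mm).
#' @slot alphaMm the alpha length parameter (mm).
#' @export
setClass("BorderCurve",
  representation(rings = "list", alphaMm = "numeric"))

setValidity("BorderCurve", function(object) {
  for (r in object@rings) {
    if (!is.matrix(r) || ncol(r) != 2L || nrow(r) < 3L)
      return("each ring must be a k x 2 matrix with k >= 3")
    if (any(!is.finite(r))) return("ring vertices must be finite")
  }
  TRUE
})

#' DistanceProfile: distances from 4th-quartile pixels to the tissue border
#'
#' Euclidean distances (mm) from each high-intensity pixel center to the
#' nearest point on the border rings, binned into half-open 3 mm intervals
#' [0,3), [3,6), ... Fractions are bin counts divided by the total number of
#' 4th-quartile pixels, so they sum to at most 1 (pixels beyond the last bin
#' edge are kept in \code{perPixelMm} but not counted in any bin).
#'
#' @slot perPixelMm per-pixel distances (mm).
#' @slot binEdgesMm bin edges, e.g. \code{c(0, 3, 6, 9, 12)}.
#' @slot binCounts integer counts per bin.
#' @slot binFractions counts / total pixels.
#' @slot nTotal total number of 4th-quartile pixels.
#' @slot nOutside pixels that fell outside all rings (assigned distance 0).
#' @export
setClass("DistanceProfile",
  representation(perPixelMm = "numeric", binEdgesMm = "numeric",
                 binCounts = "integer", binFractions = "numeric",
                 nTotal = "integer", nOutside = "integer"))

setValidity("DistanceProfile", function(object) {
  if (any(object@perPixelMm < 0)) return("distances must be >= 0")
  if (is.unsorted(object@binEdgesMm, strictly = TRUE))
    return("bin edges must be strictly increasing")
  if (length(object@binCounts) != length(object@binEdgesMm) - 1L)
    return("need one count per bin")
  if (sum(object@binCounts) > object@nTotal)
    return("bin counts exceed the number of pixels")
  TRUE
})

## ---------------------------------------------------------------------------
## Group comparisons
## ---------------------------------------------------------------------------

#' GroupComparison: a two-group rank-sum comparison
#'
#' Result of a Wilcoxon rank-sum test with per-animal (per-section) values as
#' the experimental unit. \code{method} records whether the p-value came from
#' full enumeration of group assignments ("exact") or the tie-corrected
#' normal approximation ("normal-approx").
#'
#' @slot statisticName what was compared (e.g. "clump count").
#' @slot groupA,groupB the per-section values.
#' @slot rankSum mid-rank sum of group A in the pooled ranking.
#' @slot pTwoSided two-sided p-value in (0, 1].
#' @slot method "exact" or "normal-approx".
#' @export
setClass("GroupComparison",
  representation(statisticName = "character", groupA = "numeric",
                 groupB = "numeric", rankSum = "numeric",
                 pTwoSided = "numeric", method = "character"))

setValidity("GroupComparison", function(object) {
  p <- object@pTwoSided
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p > 1)
    return("p-value must be in (0, 1]")
  if (!object@method %in% c("exact", "normal-approx"))
    return("method must be \"exact\" or \"normal-approx\"")
  TRUE
})

## ---------------------------------------------------------------------------
## Generator parameters
## ---------------------------------------------------------------------------

#' GeneratorParams: parameters of the synthetic MSI section generator
#'
#' Encodes the study conditions the generator emulates: a 50 x 125 pixel grid
#' at 400 um pitch (a ~20 x 50 mm transverse lung-lobe section), an irregular
#' connected tissue mask, and a budesonide intensity field built from
#' isotropic Gaussian foci with pattern-specific defaults:
#' \describe{
#'   \item{clumpy}{few large central foci (saline-vehicle-like patchy
#'     distribution): 4 foci, sigma 2.5 mm, no peripheral bias.}
#'   \item{dispersed}{many small foci biased toward the border
#'     (surfactant-assisted distribution): 40 foci, sigma 0.8 mm,
#'     peripheral bias 0.7.}
#'   \item{cleared}{a dispersed section whose budesonide channel is
#'     attenuated by \code{clearanceFraction} (default 0.93, matching the
#'     ~93\% loss of lung budesonide observed two hours after
#'     administration).}
#'   \item{control}{no budesonide; only the chemical background is present
#'     in the budesonide window.}
#' }
#'
#' @slot pattern one of \code{"clumpy"}, \code{"dispersed"},
#'   \code{"cleared"}, \code{"control"}.
#' @slot gridShape integer \code{c(nrow, ncol)} pixels.
#' @slot pixelPitchUm pixel pitch (micrometres, default 400).
#' @slot nBlobs number of Gaussian intensity foci.
#' @slot blobSigmaMm focus length scale (mm).
#' @slot peripheralBias fraction in [0,1] of foci placed near the border.
#' @slot baseIntensity mean intensity scale (arbitrary units).
#' @slot noiseCv coefficient of variation of the multiplicative log-normal
#'   pixel noise; 0 switches off both the multiplicative noise and the
#'   chemical-noise/background peaks (a noiseless section).
#' @slot clearanceFraction fraction of the budesonide channel removed for
#'   \code{pattern = "cleared"}.
#' @slot spcCoupling fraction in [0,1] coupling the SP-C spatial pattern to
#'   the budesonide field.
#' @slot budAmplitude override of the budesonide focus amplitude; \code{NA}
#'   uses \code{baseIntensity}. Must be 0/NA for control sections.
#' @slot seed integer RNG seed; identical parameters + seed give
#'   bit-identical sections.
#' @export
setClass("GeneratorParams",
  representation(pattern = "character", gridShape = "integer",
                 pixelPitchUm = "numeric", nBlobs = "integer",
                 blobSigmaMm = "numeric", peripheralBias = "numeric",
                 baseIntensity = "numeric", noiseCv = "numeric",
                 clearanceFraction = "numeric", spcCoupling = "numeric",
                 budAmplitude = "numeric", seed = "integer"))

setValidity("GeneratorParams", function(object) {
  msg <- character()
  inUnit <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
  if (!object@pattern %in% c("clumpy", "dispersed", "cleared", "control"))
    msg <- c(msg, "unknown pattern")
  if (length(object@gridShape) != 2L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be two positive integers")
  if (!inUnit(object@peripheralBias)) msg <- c(msg, "peripheralBias must be in [0,1]")
  if (!inUnit(object@clearanceFraction)) msg <- c(msg, "clearanceFraction must be in [0,1]")
  if (!inUnit(object@spcCoupling)) msg <- c(msg, "spcCoupling must be in [0,1]")
  if (object@blobSigmaMm <= 0) msg <- c(msg, "blobSigmaMm must be > 0")
  if (object@nBlobs < 0L) msg <- c(msg, "nBlobs must be >= 0")
  if (object@noiseCv < 0) msg <- c(msg, "noiseCv must be >= 0")
  if (object@baseIntensity <= 0) msg <- c(msg, "baseIntensity must be > 0")
  if (object@pattern == "control" && !is.na(object@budAmplitude) &&
      object@budAmplitude > 0)
    msg <- c(msg, "control sections cannot carry a nonzero budesonide amplitude")
  if (length(msg)) msg else TRUE
})

#' Construct GeneratorParams with pattern-specific defaults
#'
#' @param pattern spatial pattern of the budesonide field.
#' @param gridShape integer \code{c(nrow, ncol)}; the default 50 x 125 at
#'   400 um pitch matches a ~20 x 50 mm transverse lobe section.
#' @param pixelPitchUm pixel pitch in micrometres.
#' @param nBlobs,blobSigmaMm,peripheralBias focus model; defaults depend on
#'   \code{pattern} (see \linkS4class{GeneratorParams}).
#' @param baseIntensity intensity scale (arbitrary units).
#' @param noiseCv coefficient of variation of multiplicative noise.
#' @param clearanceFraction channel attenuation for cleared sections.
#' @param spcCoupling SP-C to budesonide spatial coupling.
#' @param budAmplitude optional focus-amplitude override.
#' @param seed RNG seed.
#' @return A \linkS4class{GeneratorParams}.
#' @examples
#' GeneratorParams("dispersed", seed = 1)
#' @export
GeneratorParams <- function(pattern = c("clumpy", "dispersed", "cleared",
                                        "control"),
                            gridShape = c(50L, 125L), pixelPitchUm = 400,
                            nBlobs = NULL, blobSigmaMm = NULL,
                            peripheralBias = NULL, baseIntensity = 1000,
                            noiseCv = 0.3, clearanceFraction = 0.93,
                            spcCoupling = 0.8, budAmplitude = NA_real_,
                            seed = 1L) {
  pattern <- match.arg(pattern)
  def <- switch(pattern,
    clumpy    = list(nBlobs = 4L,  blobSigmaMm = 2.5, peripheralBias = 0),
    dispersed = list(nBlobs = 40L, blobSigmaMm = 0.8, peripheralBias = 0.7),
    cleared   = list(nBlobs = 40L, blobSigmaMm = 0.8, peripheralBias = 0.7),
    control   = list(nBlobs = 0L,  blobSigmaMm = 0.8, peripheralBias = 0))
  new("GeneratorParams", pattern = pattern,
      gridShape = as.integer(gridShape),
      pixelPitchUm = as.numeric(pixelPitchUm),
      nBlobs = as.integer(if (is.null(nBlobs)) def$nBlobs else nBlobs),
      blobSigmaMm = as.numeric(if (is.null(blobSigmaMm)) def$blobSigmaMm
                               else blobSigmaMm),
      peripheralBias = as.numeric(if (is.null(peripheralBias))
                                  def$peripheralBias else peripheralBias),
      baseIntensity = as.numeric(baseIntensity),
      noiseCv = as.numeric(noiseCv),
      clearanceFraction = as.numeric(clearanceFraction),
      spcCoupling = as.numeric(spcCoupling),
      budAmplitude = as.numeric(budAmplitude), seed = as.integer(seed))
}
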