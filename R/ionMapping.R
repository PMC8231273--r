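## Ion-image extraction, normalization, masking and thresholding.

#' Extract a 2D ion-intensity image for one target
#'
#' Each pixel's value is the sum of centroid intensities whose m/z lies
#' within \code{toleranceDa} of the target m/z (|mz - target| <= tolerance).
#' Summing is robust to centroid splitting; use \code{aggregate = "max"} to
#' take the most intense in-window centroid instead. Grid cells with no
#' acquired spectrum are missing (\code{NA}); acquired pixels with no peak in
#' the window are 0.
#'
#' @param dataset an \linkS4class{MSIDataset}.
#' @param target an \linkS4class{IonTarget} whose window overlaps the
#'   dataset's m/z range.
#' @param aggregate \code{"sum"} (default) or \code{"max"}.
#' @return An \linkS4class{IonImage}.
#' @export
extractIonImage <- function(dataset, target, aggregate = c("sum", "max")) {
  aggregate <- match.arg(aggregate)
  lo <- target@targetMz - target@toleranceDa
  hi <- target@targetMz + target@toleranceDa
  if (hi < dataset@mzRange[1L] || lo > dataset@mzRange[2L])
    stop(sprintf(
      "extraction window %.4f-%.4f for '%s' lies outside the dataset m/z range %.3f-%.3f",
      lo, hi, target@name, dataset@mzRange[1L], dataset@mzRange[2L]))
  agg <- if (aggregate == "sum") sum else function(x) if (length(x)) max(x) else 0
  vals <- vapply(dataset@spectra, function(s) {
    if (!length(s$mz)) return(0)
    i1 <- findInterval(lo, s$mz, left.open = TRUE) + 1L
    i2 <- findInterval(hi, s$mz)
    if (i2 < i1) 0 else agg(s$intensity[i1:i2])
  }, numeric(1))
  m <- matrix(NA_real_, dataset@gridDim[1L], dataset@gridDim[2L])
  m[cbind(dataset@coords[, 2L] + 1L, dataset@coords[, 1L] + 1L)] <- vals
  IonImage(m, pixelPitchUm = dataset@pixelPitchUm, target = target,
           sectionId = dataset@sectionId)
}

#' Normalize an analyte image by an internal-standard image
#'
#' Per-pixel ratio analyte / reference. Pixels where the reference is
#' missing, zero or negative become missing and are counted in the returned
#' image's \code{dropTally}.
#'
#' @param analyte,reference \linkS4class{IonImage}s of the same shape and
#'   section.
#' @return An \linkS4class{IonImage} of normalized intensities.
#' @export
normalizeImage <- function(analyte, reference) {
  .checkSameShape(analyte@values, reference@values, "analyte and reference")
  a <- analyte@values; r <- reference@values
  bad <- !is.na(a) & (is.na(r) | r <= 0)
  out <- a / r
  out[is.na(r) | r <= 0] <- NA_real_
  IonImage(out, pixelPitchUm = analyte@pixelPitchUm, target = analyte@target,
           sectionId = analyte@sectionId,
           dropTally = analyte@dropTally + sum(bad))
}

#' Estimate the tissue mask from the heme channel
#'
#' On-tissue pixels are those whose heme intensity exceeds
#' \code{minFraction} times the median of the positive heme intensities;
#' only the largest connected component is kept, so stray off-tissue
#' specks do not enter the mask.
#'
#' @param heme heme-channel \linkS4class{IonImage}.
#' @param minFraction threshold as a fraction of the median positive heme
#'   intensity (default 0.05).
#' @param connectivity adjacency used for the component filter.
#' @return A \linkS4class{TissueMask}.
#' @export
tissueMaskFromHeme <- function(heme, minFraction = 0.05,
                               connectivity = c("8-neighbor", "4-neighbor")) {
  connectivity <- match.arg(connectivity)
  v <- heme@values
  pos <- v[!is.na(v) & v > 0]
  if (!length(pos))
    stop("no tissue detectable: heme image has no positive intensities")
  thr <- minFraction * stats::median(pos)
  on <- !is.na(v) & v > thr
  lab <- .labelComponents(on, connectivity)
  if (any(on)) {
    sizes <- tabulate(lab[!is.na(lab)])
    keep <- which.max(sizes)
    on <- !is.na(lab) & lab == keep
  }
  TissueMask(on, source = heme@target@name,
             pixelPitchUm = heme@pixelPitchUm)
}

#' Control-derived intensity threshold
#'
#' Pools the on-tissue (normalized) intensities of the budesonide-free
#' control sections and returns the given quantile (linear-interpolation
#' convention, \code{stats::quantile} type 7). Signal above this threshold
#' in treated sections is considered detected drug.
#'
#' @param controlImages list of control \linkS4class{IonImage}s.
#' @param masks list of matching \linkS4class{TissueMask}s.
#' @param quantile quantile in (0, 1], default 0.99.
#' @return The threshold (single number, normalized-intensity units).
#' @export
controlThreshold <- function(controlImages, masks, quantile = 0.99) {
  if (!length(controlImages)) stop("need at least one control image")
  if (length(controlImages) != length(masks))
    stop("need one mask per control image")
  if (quantile <= 0 || quantile > 1) stop("quantile must be in (0, 1]")
  pool <- unlist(Map(function(img, msk) {
    .checkSameShape(img@values, msk@onTissue, "control image and mask")
    v <- img@values[msk@onTissue]
    v[!is.na(v)]
  }, controlImages, masks))
  if (!length(pool)) stop("empty control pool: no on-tissue pixels")
  unname(stats::quantile(pool, probs = quantile, type = 7))
}

#' Keep only above-threshold on-tissue signal
#'
#' Values at or below the threshold, and off-tissue pixels, become missing;
#' surviving values are unchanged.
#'
#' @param image an \linkS4class{IonImage}.
#' @param mask the section's \linkS4class{TissueMask}.
#' @param threshold intensity threshold (same scale as \code{image}).
#' @return An \linkS4class{IonImage}.
#' @export
aboveThresholdMap <- function(image, mask, threshold) {
  .checkSameShape(image@values, mask@onTissue, "image and mask")
  v <- image@values
  v[!mask@onTissue | is.na(v) | v <= threshold] <- NA_real_
  IonImage(v, pixelPitchUm = image@pixelPitchUm, target = image@target,
           sectionId = image@sectionId, scaleType = image@scaleType)
}

#' Log-intensity values of on-tissue pixels
#'
#' Natural logarithm of the strictly positive on-tissue intensities (the
#' violin-plot export); non-positive values are excluded and tallied.
#'
#' @param image an \linkS4class{IonImage}.
#' @param mask the section's \linkS4class{TissueMask}.
#' @return \code{list(logIntensity = numeric, droppedNonpositive = integer)}.
#' @export
logIntensityValues <- function(image, mask) {
  .checkSameShape(image@values, mask@onTissue, "image and mask")
  v <- image@values[mask@onTissue]
  v <- v[!is.na(v)]
  list(logIntensity = log(v[v > 0]),
       droppedNonpositive = sum(v <= 0))
}
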