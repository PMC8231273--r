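## Accessors and show methods.

#' @rdname accessors
#' @export
setMethod("pixelPitch", "MSIDataset", function(x) x@pixelPitchUm)
#' @rdname accessors
#' @export
setMethod("pixelPitch", "IonImage", function(x) x@pixelPitchUm)
#' @rdname accessors
#' @export
setMethod("pixelPitch", "TissueMask", function(x) x@pixelPitchUm)
#' @rdname accessors
#' @export
setMethod("pixelPitch", "QuartileMap", function(x) x@pixelPitchUm)

#' @rdname accessors
#' @export
setMethod("intensityValues", "IonImage", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("maskMatrix", "TissueMask", function(x) x@onTissue)

#' @rdname accessors
#' @export
setMethod("quartileLabels", "QuartileMap", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("clumpPixels", "ClumpSet", function(x) x@clumps)

#' @rdname accessors
#' @export
setMethod("clumpSizes", "ClumpSet", function(x)
  vapply(x@clumps, nrow, integer(1)))

#' @rdname accessors
#' @export
setMethod("borderRings", "BorderCurve", function(x) x@rings)

#' @rdname accessors
#' @export
setMethod("spectra", "MSIDataset", function(x) x@spectra)

#' @rdname accessors
#' @export
setMethod("pixelCoords", "MSIDataset", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("sectionId", "MSIDataset", function(x) x@sectionId)
#' @rdname accessors
#' @export
setMethod("sectionId", "IonImage", function(x) x@sectionId)

#' @rdname accessors
#' @export
setMethod("groupLabel", "MSIDataset", function(x) x@groupLabel)

#' @rdname accessors
#' @export
setMethod("mzRange", "MSIDataset", function(x) x@mzRange)

#' @rdname accessors
#' @export
setMethod("gridDim", "MSIDataset", function(x) x@gridDim)
#' @rdname accessors
#' @export
setMethod("gridDim", "ClumpSet", function(x) x@gridDim)

#' @rdname accessors
#' @export
setMethod("pValue", "GroupComparison", function(x) x@pTwoSided)

setMethod("show", "IonTarget", function(object) {
  cat(sprintf("IonTarget '%s': m/z %.4f +/- %.4g Da%s\n", object@name,
              object@targetMz, object@toleranceDa,
              if (is.na(object@formula)) "" else
                sprintf(" [%s, charge %+d]", object@formula,
                        as.integer(object@charge))))
})

setMethod("show", "MSIDataset", function(object) {
  cat(sprintf(
    "MSIDataset '%s'%s: %d pixels on a %d x %d grid (%.0f um pitch), m/z %.3f-%.3f\n",
    object@sectionId,
    if (nzchar(object@groupLabel)) sprintf(" [%s]", object@groupLabel) else "",
    nrow(object@coords), object@gridDim[1L], object@gridDim[2L],
    object@pixelPitchUm, object@mzRange[1L], object@mzRange[2L]))
})

setMethod("show", "IonImage", function(object) {
  v <- object@values
  cat(sprintf(
    "IonImage '%s' (%s scale): %d x %d grid, %d non-missing pixels%s\n",
    object@target@name, object@scaleType, nrow(v), ncol(v), sum(!is.na(v)),
    if (object@dropTally > 0L)
      sprintf(" (%d dropped)", object@dropTally) else ""))
})

setMethod("show", "TissueMask", function(object) {
  cat(sprintf("TissueMask from '%s': %d of %d pixels on tissue\n",
              object@source, sum(object@onTissue), length(object@onTissue)))
})

setMethod("show", "QuartileMap", function(object) {
  cat(sprintf("QuartileMap for '%s': %d tissue pixels, class sizes %s\n",
              object@sourceSection, sum(!is.na(object@labels)),
              paste(tabulate(object@labels[!is.na(object@labels)], 4L),
                    collapse = "/")))
})

setMethod("show", "ClumpSet", function(object) {
  sz <- vapply(object@clumps, nrow, integer(1))
  cat(sprintf("ClumpSet (%s): %d clumps, median size %s px\n",
              object@connectivity, length(sz),
              if (length(sz)) format(stats::median(sz)) else "NA"))
})

setMethod("show", "BorderCurve", function(object) {
  cat(sprintf("BorderCurve (alpha = %.3g mm): %d ring(s), %s vertices\n",
              object@alphaMm, length(object@rings),
              paste(vapply(object@rings, nrow, integer(1)), collapse = "+")))
})

setMethod("show", "DistanceProfile", function(object) {
  cat(sprintf(
    "DistanceProfile: %d pixels, bins [%s) mm, fractions %s\n",
    object@nTotal, paste(object@binEdgesMm, collapse = ","),
    paste(sprintf("%.3f", object@binFractions), collapse = "/")))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf(
    "GroupComparison '%s' (%s): n = %d vs %d, rank sum = %.1f, p = %.4g\n",
    object@statisticName, object@method, length(object@groupA),
    length(object@groupB), object@rankSum, object@pTwoSided))
})

setMethod("show", "GeneratorParams", function(object) {
  cat(sprintf(
    "GeneratorParams '%s': %d x %d px at %.0f um, %d foci (sigma %.2g mm), seed %d\n",
    object@pattern, object@gridShape[1L], object@gridShape[2L],
    object@pixelPitchUm, object@nBlobs, object@blobSigmaMm, object@seed))
})
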