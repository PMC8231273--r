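#' Accessor generics
#'
#' Small accessor layer over the package's S4 containers so user code never
#' touches slots directly.
#'
#' @param x an object from this package.
#' @name accessors
NULL

#' @rdname accessors
#' @return \code{pixelPitch} returns the pixel pitch in micrometres.
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))

#' @rdname accessors
#' @return \code{intensityValues} returns the raster matrix of an IonImage.
#' @export
setGeneric("intensityValues", function(x) standardGeneric("intensityValues"))

#' @rdname accessors
#' @return \code{maskMatrix} returns the logical on-tissue matrix.
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname accessors
#' @return \code{quartileLabels} returns the integer label matrix.
#' @export
setGeneric("quartileLabels", function(x) standardGeneric("quartileLabels"))

#' @rdname accessors
#' @return \code{clumpPixels} returns the list of clump coordinate matrices.
#' @export
setGeneric("clumpPixels", function(x) standardGeneric("clumpPixels"))

#' @rdname accessors
#' @return \code{clumpSizes} returns the integer vector of clump sizes.
#' @export
setGeneric("clumpSizes", function(x) standardGeneric("clumpSizes"))

#' @rdname accessors
#' @return \code{borderRings} returns the list of ring vertex matrices (mm).
#' @export
setGeneric("borderRings", function(x) standardGeneric("borderRings"))

#' @rdname accessors
#' @return \code{spectra} returns the list of per-pixel peak lists.
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' @rdname accessors
#' @return \code{pixelCoords} returns the 0-based (x, y) coordinate matrix.
#' @export
setGeneric("pixelCoords", function(x) standardGeneric("pixelCoords"))

#' @rdname accessors
#' @return \code{sectionId} returns the section identifier.
#' @export
setGeneric("sectionId", function(x) standardGeneric("sectionId"))

#' @rdname accessors
#' @return \code{groupLabel} returns the treatment-group label.
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname accessors
#' @return \code{mzRange} returns the acquisition m/z range.
#' @export
setGeneric("mzRange", function(x) standardGeneric("mzRange"))

#' @rdname accessors
#' @return \code{gridDim} returns the bounding grid \code{c(nrow, ncol)}.
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname accessors
#' @return \code{pValue} returns the two-sided p-value.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
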