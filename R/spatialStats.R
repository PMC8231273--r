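## Per-section spatial statistics: standardization, quartile binning, clump
## detection, alpha-hull tissue border, distance-to-border profiles and a
## colocalization score.

#' Scale and mean-center a section
#'
#' Transforms the on-tissue values to z-scores using the on-tissue sample
#' mean and standard deviation. Standardization operates on the normalized
#' linear intensities (not log).
#'
#' @param image an \linkS4class{IonImage}.
#' @param mask the section's \linkS4class{TissueMask}.
#' @return An \linkS4class{IonImage} with \code{scaleType = "zscore"}.
#' @export
zscoreSection <- function(image, mask) {
  .checkSameShape(image@values, mask@onTissue, "image and mask")
  v <- image@values
  sel <- mask@onTissue & !is.na(v)
  x <- v[sel]
  if (length(x) < 2L) stop("need at least 2 on-tissue pixels to standardize")
  s <- stats::sd(x)
  if (s == 0) stop("constant section: zero dispersion, cannot standardize")
  out <- matrix(NA_real_, nrow(v), ncol(v))
  out[sel] <- (x - mean(x)) / s
  IonImage(out, pixelPitchUm = image@pixelPitchUm, target = image@target,
           sectionId = image@sectionId, scaleType = "zscore",
           dropTally = image@dropTally)
}

#' Bin tissue pixels into intensity quartiles
#'
#' Rank-based binning: on-tissue pixels are ranked ascending (ties broken by
#' row-major pixel order, deterministically) and rank r of n maps to label
#' \code{ceiling(4 r / n)}, so the four classes partition the tissue with
#' sizes differing by at most one pixel. Because only ranks matter, binning
#' is invariant under any strictly monotone transform of the intensities;
#' z-scoring first does not change the labels.
#'
#' @param image an \linkS4class{IonImage} (intensity or z-score scale).
#' @param mask the section's \linkS4class{TissueMask}.
#' @return A \linkS4class{QuartileMap}.
#' @export
quartileBin <- function(image, mask) {
  .checkSameShape(image@values, mask@onTissue, "image and mask")
  v <- image@values
  sel <- mask@onTissue & !is.na(v)
  n <- sum(sel)
  if (n < 4L) stop("need at least 4 on-tissue pixels to bin in quartiles")
  idx <- which(t(sel))          # row-major order of tissue pixels
  vm <- t(v)[idx]
  ord <- order(vm)              # stable: ties keep row-major order
  rank <- integer(n); rank[ord] <- seq_len(n)
  lab4 <- as.integer(ceiling(4 * rank / n))
  labT <- matrix(NA_integer_, ncol(v), nrow(v))
  labT[idx] <- lab4
  new("QuartileMap", labels = t(labT), sourceSection = image@sectionId,
      pixelPitchUm = image@pixelPitchUm)
}

#' Detect clumps of high-intensity pixels
#'
#' Connected components of 4th-quartile pixels under the declared adjacency
#' (default 8-neighbor "queen" connectivity). Singleton pixels are clumps of
#' size 1; a map with no 4th-quartile pixels gives an empty set.
#'
#' @param qmap a \linkS4class{QuartileMap}.
#' @param connectivity \code{"8-neighbor"} (default) or \code{"4-neighbor"}.
#' @return A \linkS4class{ClumpSet}.
#' @export
findClumps <- function(qmap, connectivity = c("8-neighbor", "4-neighbor")) {
  connectivity <- match.arg(connectivity)
  fg <- !is.na(qmap@labels) & qmap@labels == 4L
  lab <- .labelComponents(fg, connectivity)
  ids <- lab[!is.na(lab)]
  clumps <- if (length(ids)) {
    lapply(seq_len(max(ids)), function(k) .maskCoords(!is.na(lab) & lab == k))
  } else list()
  new("ClumpSet", clumps = clumps, connectivity = connectivity,
      gridDim = as.integer(dim(qmap@labels)))
}

#' Clump count and median size
#'
#' @param clumps a \linkS4class{ClumpSet}.
#' @return \code{list(count =, medianSizePx =)}; the median of an empty set
#'   is \code{NA}.
#' @export
clumpSummary <- function(clumps) {
  sz <- clumpSizes(clumps)
  list(count = length(sz),
       medianSizePx = if (length(sz)) stats::median(as.numeric(sz))
                      else NA_real_)
}

## ---------------------------------------------------------------------------
## Alpha-hull tissue border
## ---------------------------------------------------------------------------

## Physical (mm) coordinates of pixel centers: x along columns, y along rows.
.pixelCentersMm <- function(coords, pitchUm) {
  pitch <- pitchUm / 1000
  cbind(x = (coords[, 1L] + 0.5) * pitch, y = (coords[, 2L] + 0.5) * pitch)
}

## Alpha-shape boundary edges of a point set via the classic circle
## criterion: an edge (p, q) with |p - q| <= 2 alpha is on the boundary iff
## one of the two radius-alpha circles through p and q contains no other
## point strictly inside. Candidate vertices are restricted to mask-boundary
## pixels, which is exact for alpha >= pixel pitch (interior grid points
## always have a neighbor inside any radius->=pitch disk through them).
.alphaEdges <- function(ptsAll, isCandidate, alpha) {
  eps <- 1e-9
  cand <- which(isCandidate)
  edges <- matrix(integer(0), 0L, 2L)
  ## spatial bucketing of all points for disk-emptiness queries
  cell <- alpha
  bx <- floor(ptsAll[, 1L] / cell); by <- floor(ptsAll[, 2L] / cell)
  key <- paste(bx, by)
  buckets <- split(seq_len(nrow(ptsAll)), key)
  nearPoints <- function(cx, cy) {
    kx <- floor(cx / cell); ky <- floor(cy / cell)
    keys <- as.vector(outer((kx - 1):(kx + 1), (ky - 1):(ky + 1), paste))
    unlist(buckets[keys], use.names = FALSE)
  }
  emptyDisk <- function(cx, cy, i, j) {
    idx <- nearPoints(cx, cy)
    idx <- idx[idx != i & idx != j]
    if (!length(idx)) return(TRUE)
    d2 <- (ptsAll[idx, 1L] - cx)^2 + (ptsAll[idx, 2L] - cy)^2
    all(d2 >= (alpha - eps)^2)
  }
  out <- vector("list", length(cand))
  nOut <- 0L
  for (ii in seq_along(cand)) {
    i <- cand[ii]
    for (j in cand[cand > i]) {
      dx <- ptsAll[j, 1L] - ptsAll[i, 1L]
      dy <- ptsAll[j, 2L] - ptsAll[i, 2L]
      d2 <- dx * dx + dy * dy
      if (d2 > (2 * alpha)^2) next
      mx <- (ptsAll[i, 1L] + ptsAll[j, 1L]) / 2
      my <- (ptsAll[i, 2L] + ptsAll[j, 2L]) / 2
      h <- sqrt(max(0, alpha^2 - d2 / 4))
      d <- sqrt(d2)
      nx <- -dy / d; ny <- dx / d
      if (emptyDisk(mx + h * nx, my + h * ny, i, j) ||
          emptyDisk(mx - h * nx, my - h * ny, i, j)) {
        nOut <- nOut + 1L
        out[[nOut]] <- c(i, j)
      }
    }
  }
  if (nOut) do.call(rbind, out[seq_len(nOut)]) else edges
}

## Assemble boundary edges into closed rings. At degree-2 vertices the walk
## is forced; at degenerate higher-degree vertices the unused edge making the
## sharpest clockwise turn is taken.
.assembleRings <- function(pts, edges) {
  if (!nrow(edges)) stop("alpha hull produced no boundary edges")
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  used <- new.env(parent = emptyenv())
  adj <- split(c(edges[, 2L], edges[, 1L]), c(edges[, 1L], edges[, 2L]))
  adj <- lapply(adj, unique)
  rings <- list()
  isUsed <- function(a, b) isTRUE(get0(ekey(a, b), envir = used))
  markUsed <- function(a, b) assign(ekey(a, b), TRUE, envir = used)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    if (isUsed(a, b)) next
    ring <- c(a, b)
    markUsed(a, b)
    prev <- a; curr <- b
    repeat {
      nbrs <- adj[[as.character(curr)]]
      nbrs <- nbrs[!vapply(nbrs, function(w) isUsed(curr, w), logical(1))]
      if (!length(nbrs)) break
      if (length(nbrs) == 1L) {
        nxt <- nbrs
      } else {
        ## sharpest clockwise continuation relative to the incoming direction
        vin <- pts[curr, ] - pts[prev, ]
        ang <- vapply(nbrs, function(w) {
          vout <- pts[w, ] - pts[curr, ]
          a2 <- atan2(vin[1L] * vout[2L] - vin[2L] * vout[1L],
                      sum(vin * vout))
          a2
        }, numeric(1))
        nxt <- nbrs[which.max(ang)]
      }
      markUsed(curr, nxt)
      if (nxt == ring[1L]) break
      ring <- c(ring, nxt)
      prev <- curr; curr <- nxt
    }
    if (length(ring) >= 3L) rings[[length(rings) + 1L]] <- ring
  }
  if (!length(rings)) stop("alpha hull boundary could not be closed")
  lapply(rings, function(r) {
    m <- pts[r, , drop = FALSE]
    colnames(m) <- c("x", "y")
    m
  })
}

#' Alpha-hull border of the tissue
#'
#' Computes the alpha shape of the on-tissue pixel centers (in physical mm)
#' and returns its boundary as one or more closed rings. An edge belongs to
#' the boundary when a circle of radius \code{alphaMm} through its two
#' endpoints contains no other tissue pixel center; in the large-alpha limit
#' this is the convex hull, and \code{alphaMm >= } the mask diameter takes
#' that exact path. \code{alphaMm} below the pixel pitch is rejected (the
#' boundary of a raster mask is not resolved below the raster step).
#'
#' @param mask a \linkS4class{TissueMask} with at least 3 tissue pixels.
#' @param alphaMm alpha length parameter in mm; default 3 x pixel pitch
#'   (1.2 mm at 400 um), the smallest value that keeps typical lobe masks
#'   single-ringed.
#' @return A \linkS4class{BorderCurve}.
#' @export
alphaHullBorder <- function(mask, alphaMm = 3 * mask@pixelPitchUm / 1000) {
  fg <- mask@onTissue
  if (sum(fg) < 3L) stop("need at least 3 on-tissue pixels")
  pitch <- mask@pixelPitchUm / 1000
  coords <- .maskCoords(fg)
  pts <- .pixelCentersMm(coords, mask@pixelPitchUm)
  ## collinear point sets have no area to bound
  if (all(coords[, 1L] == coords[1L, 1L]) ||
      all(coords[, 2L] == coords[1L, 2L]))
    stop("tissue pixels are collinear; no border can be estimated")
  if (alphaMm < pitch - 1e-12)
    stop(sprintf("alphaMm (%.3g mm) must be at least the pixel pitch (%.3g mm)",
                 alphaMm, pitch))
  diam <- sqrt(max(
    (max(pts[, 1L]) - min(pts[, 1L]))^2 + (max(pts[, 2L]) - min(pts[, 2L]))^2))
  if (alphaMm >= diam) {
    hull <- grDevices::chull(pts)
    ring <- pts[hull, , drop = FALSE]
    colnames(ring) <- c("x", "y")
    return(new("BorderCurve", rings = list(ring), alphaMm = alphaMm))
  }
  ## candidate vertices: mask-boundary pixels (8-neighborhood incomplete)
  nr <- nrow(fg); nc <- ncol(fg)
  padded <- matrix(FALSE, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- fg
  full <- padded[2:(nr + 1L), 2:(nc + 1L)]
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc)
      full <- full & padded[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  boundary <- fg & !full
  bcoord <- .maskCoords(boundary)
  isCand <- (coords[, 1L] + 1e6 * coords[, 2L]) %in%
    (bcoord[, 1L] + 1e6 * bcoord[, 2L])
  edges <- .alphaEdges(pts, isCand, alphaMm)
  rings <- .assembleRings(pts, edges)
  new("BorderCurve", rings = rings, alphaMm = alphaMm)
}

#' Distance-to-border profile of high-intensity pixels
#'
#' Euclidean distance (mm) from each 4th-quartile pixel center to the
#' nearest point on the border rings, binned into half-open intervals
#' \code{[0,3), [3,6), ...} by default. Fractions are counts divided by the
#' total number of 4th-quartile pixels. Pixels falling outside all rings
#' (possible with a small alpha) are assigned distance 0 and tallied in
#' \code{nOutside}.
#'
#' @param pixels 4th-quartile pixels: a \linkS4class{ClumpSet}, a
#'   \linkS4class{QuartileMap}, or an n x 2 matrix of 0-based (x, y)
#'   coordinates.
#' @param border a \linkS4class{BorderCurve}.
#' @param pitchUm pixel pitch in micrometres.
#' @param binEdgesMm bin edges in mm, default \code{c(0, 3, 6, 9, 12)}.
#' @return A \linkS4class{DistanceProfile}.
#' @export
distanceProfile <- function(pixels, border, pitchUm,
                            binEdgesMm = c(0, 3, 6, 9, 12)) {
  coords <- if (is(pixels, "ClumpSet")) {
    if (length(pixels@clumps)) do.call(rbind, pixels@clumps)
    else matrix(integer(0), 0L, 2L)
  } else if (is(pixels, "QuartileMap")) {
    .maskCoords(!is.na(pixels@labels) & pixels@labels == 4L)
  } else as.matrix(pixels)
  n <- nrow(coords)
  if (n == 0L)
    return(new("DistanceProfile", perPixelMm = numeric(0),
               binEdgesMm = as.numeric(binEdgesMm),
               binCounts = integer(length(binEdgesMm) - 1L),
               binFractions = rep(NaN, length(binEdgesMm) - 1L),
               nTotal = 0L, nOutside = 0L))
  pts <- .pixelCentersMm(coords, pitchUm)
  d <- rep(Inf, n)
  for (ring in border@rings) d <- pmin(d, .distToRing(pts, ring))
  ## pixels outside all rings get distance 0
  bnd <- do.call(rbind, lapply(border@rings, function(r)
    rbind(r, c(NA, NA))))
  inside <- mgcv::in.out(bnd, pts)
  onRing <- d <= 1e-9
  outside <- !inside & !onRing
  d[outside] <- 0
  counts <- vapply(seq_len(length(binEdgesMm) - 1L), function(k)
    sum(d >= binEdgesMm[k] & d < binEdgesMm[k + 1L]), integer(1))
  new("DistanceProfile", perPixelMm = d,
      binEdgesMm = as.numeric(binEdgesMm), binCounts = counts,
      binFractions = counts / n, nTotal = as.integer(n),
      nOutside = as.integer(sum(outside)))
}

#' Rank-correlation colocalization score
#'
#' Spearman rank correlation between two channels over the shared
#' non-missing on-tissue pixels; quantifies, e.g., how closely the SP-C
#' distribution tracks the budesonide distribution in consecutive sections.
#'
#' @param imageA,imageB \linkS4class{IonImage}s on the same grid.
#' @param mask the section's \linkS4class{TissueMask}.
#' @return Rank correlation in [-1, 1].
#' @export
colocalizationScore <- function(imageA, imageB, mask) {
  .checkSameShape(imageA@values, imageB@values, "the two images")
  .checkSameShape(imageA@values, mask@onTissue, "images and mask")
  sel <- mask@onTissue & !is.na(imageA@values) & !is.na(imageB@values)
  if (sum(sel) < 3L) stop("need at least 3 shared non-missing tissue pixels")
  a <- imageA@values[sel]; b <- imageB@values[sel]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: constant input channel")
  stats::cor(a, b, method = "spearman")
}
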