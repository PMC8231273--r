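## Internal raster utilities.

## Shift a matrix by (dr, dc), filling vacated cells with `fill`.
.shiftMatrix <- function(m, dr, dc, fill = Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

.neighborOffsets <- function(connectivity) {
  four <- cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  if (connectivity == "4-neighbor") four else
    rbind(four, cbind(dr = c(-1L, -1L, 1L, 1L), dc = c(-1L, 1L, -1L, 1L)))
}

## Connected components of a logical matrix by iterative minimum-label
## propagation. Returns an integer matrix of component ids (NA off the
## foreground), ids numbered in column-major order of first occurrence, so
## labeling is fully deterministic.
.labelComponents <- function(fg, connectivity = "8-neighbor") {
  stopifnot(is.logical(fg))
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(Inf, nr, nc)
  lab[fg] <- which(fg)
  offs <- .neighborOffsets(connectivity)
  repeat {
    new <- lab
    for (k in seq_len(nrow(offs)))
      new <- pmin(new, .shiftMatrix(lab, offs[k, 1L], offs[k, 2L]))
    new[!fg] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(NA_integer_, nr, nc)
  if (any(fg)) {
    ids <- lab[fg]  # column-major order; ids numbered by first occurrence
    out[fg] <- match(ids, unique(ids))
  }
  out
}

## 0-based (x, y) coordinates of TRUE cells, column x = column index - 1.
.maskCoords <- function(fg) {
  idx <- which(fg, arr.ind = TRUE)
  cbind(x = idx[, 2L] - 1L, y = idx[, 1L] - 1L)
}

## Distance (in pixels) from each TRUE cell to the nearest border cell of the
## mask (border = TRUE cell with an off-mask or off-grid 4-neighbor).
## Returns a matrix with NA off mask.
.borderDistancePx <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  padded <- matrix(FALSE, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- fg
  inner <- padded[2:(nr + 1L), 2:(nc + 1L)] &
    padded[1:nr, 2:(nc + 1L)] & padded[3:(nr + 2L), 2:(nc + 1L)] &
    padded[2:(nr + 1L), 1:nc] & padded[2:(nr + 1L), 3:(nc + 2L)]
  border <- fg & !inner
  out <- matrix(NA_real_, nr, nc)
  if (!any(border)) { out[fg] <- 0; return(out) }
  bi <- which(border, arr.ind = TRUE)
  ti <- which(fg, arr.ind = TRUE)
  d2 <- outer(ti[, 1L], bi[, 1L], "-")^2 + outer(ti[, 2L], bi[, 2L], "-")^2
  out[fg] <- sqrt(apply(d2, 1L, min))
  out
}

## Minimum distance from points (n x 2) to a closed polyline (k x 2,
## implicitly closed). Vectorized over points, looping over segments.
.distToRing <- function(pts, ring) {
  k <- nrow(ring)
  a <- ring
  b <- ring[c(2:k, 1L), , drop = FALSE]
  best <- rep(Inf, nrow(pts))
  for (s in seq_len(k)) {
    ax <- a[s, 1L]; ay <- a[s, 2L]
    dx <- b[s, 1L] - ax; dy <- b[s, 2L] - ay
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d <- sqrt((pts[, 1L] - ax)^2 + (pts[, 2L] - ay)^2)
    } else {
      t <- ((pts[, 1L] - ax) * dx + (pts[, 2L] - ay) * dy) / len2
      t <- pmin(1, pmax(0, t))
      d <- sqrt((pts[, 1L] - (ax + t * dx))^2 + (pts[, 2L] - (ay + t * dy))^2)
    }
    best <- pmin(best, d)
  }
  best
}

## Shared input checks -------------------------------------------------------

.checkSameShape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop("shape mismatch between ", what, call. = FALSE)
  invisible(TRUE)
}
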