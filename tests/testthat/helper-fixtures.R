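## Shared fixtures and independent oracles for the test suite.

## A tiny MSIDataset with explicit peak lists on a small grid.
makeTinyDataset <- function(peakLists, ncolGrid = NULL, nrowGrid = NULL,
                            mzRange = c(185, 650), pitch = 400,
                            sectionId = "tiny") {
  n <- length(peakLists)
  if (is.null(ncolGrid)) ncolGrid <- n
  if (is.null(nrowGrid)) nrowGrid <- ceiling(n / ncolGrid)
  co <- cbind(x = (seq_len(n) - 1L) %% ncolGrid,
              y = (seq_len(n) - 1L) %/% ncolGrid)
  MSIDataset(peakLists, co, c(nrowGrid, ncolGrid), pitch, mzRange,
             sectionId = sectionId)
}

## A random small MSIDataset for round-trip property tests.
randomDataset <- function(maxSide = 4L) {
  nr <- sample(1:maxSide, 1L); nc <- sample(1:maxSide, 1L)
  n <- sample(1:(nr * nc), 1L)
  cells <- sample(nr * nc, n)
  co <- cbind(x = (cells - 1L) %% nc, y = (cells - 1L) %/% nc)
  sp <- lapply(seq_len(n), function(i) {
    k <- sample(0:6, 1L)
    list(mz = sort(stats::runif(k, 190, 640)),
         intensity = stats::runif(k, 0, 1e4))
  })
  MSIDataset(sp, co, c(nr, nc), 400, c(185, 650),
             sectionId = sprintf("rand%d", sample.int(1e6, 1L)))
}

## An IonImage directly from a matrix (NA = missing).
makeImage <- function(values, pitch = 400, scaleType = "intensity",
                      name = "budesonide", targetMz = 564.308) {
  IonImage(values, pixelPitchUm = pitch,
           target = IonTarget(name, targetMz, 0.005),
           sectionId = "img", scaleType = scaleType)
}

makeMask <- function(onTissue, pitch = 400) {
  TissueMask(onTissue, source = "heme", pixelPitchUm = pitch)
}

## Independent connected-component oracle: recursive flood fill with an
## explicit stack, structured nothing like the label-propagation
## implementation.
floodFillLabels <- function(fg, connectivity = "8-neighbor") {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(NA_integer_, nr, nc)
  offs <- if (connectivity == "4-neighbor")
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  comp <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!fg[i, j] || !is.na(lab[i, j])) next
    comp <- comp + 1L
    stack <- list(c(i, j))
    lab[i, j] <- comp
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in offs) {
        r <- cur[1L] + o[1L]; c2 <- cur[2L] + o[2L]
        if (r >= 1L && r <= nr && c2 >= 1L && c2 <= nc &&
            fg[r, c2] && is.na(lab[r, c2])) {
          lab[r, c2] <- comp
          stack[[length(stack) + 1L]] <- c(r, c2)
        }
      }
    }
  }
  lab
}

## Component signature that is invariant to label numbering: sorted list of
## sorted cell-index sets.
componentSignature <- function(lab) {
  ids <- lab[!is.na(lab)]
  if (!length(ids)) return(list())
  groups <- split(which(!is.na(lab)), lab[!is.na(lab)])
  unname(groups[order(vapply(groups, min, numeric(1)))])
}

## Independent exact Wilcoxon oracle: enumerate subsets via bit masks.
wilcoxonOracle <- function(a, b) {
  nA <- length(a); n <- nA + length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(nA)])
  ws <- numeric(0)
  for (m in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(m))[1:n]
    if (sum(bits) == nA) ws <- c(ws, sum(r[bits == 1L]))
  }
  eps <- 1e-9
  min(1, 2 * min(mean(ws <= w + eps), mean(ws >= w - eps)))
}

## Clump statistics for one synthetic section (no imzML round trip).
sectionClumpStats <- function(section, registry = ionTargetRegistry(),
                              connectivity = "8-neighbor") {
  bud <- extractIonImage(section$budesonide, registry$budesonide)
  isI <- extractIonImage(section$budesonide, registry$internal_standard)
  heme <- extractIonImage(section$budesonide, registry$heme)
  msk <- tissueMaskFromHeme(heme)
  bn <- normalizeImage(bud, isI)
  qm <- quartileBin(zscoreSection(bn, msk), msk)
  clumps <- findClumps(qm, connectivity)
  list(clumps = clumps, summary = clumpSummary(clumps), mask = msk,
       normalized = bn, quartileMap = qm)
}
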